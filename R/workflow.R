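# End-to-end pipeline orchestration: simulate -> QC -> structure -> painting
# -> ancestry -> diversity -> uniparental -> social model, from one config,
# with per-stage seeds derived from a master seed and a checksummed manifest.

#' Default pipeline configuration
#'
#' A small three-source demonstration configuration (European,
#' Gulf-of-Guinea and Angolan source populations; one admixed
#' island-community cohort plus reference cohorts) that runs every stage in
#' a few seconds. Any element can be overridden through `run_pipeline()`'s
#' `config` argument.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    master_seed = 1L,
    out_dir = tempfile("pipeline_"),
    stages = list(simdata = TRUE, qc = TRUE, structure = TRUE,
                  painting = TRUE, ancestry = TRUE, diversity = TRUE,
                  uniparental = TRUE, social = TRUE),
    simdata = list(
      n_sites = 2000,
      fst = c(eur = 0.16, gog = 0.03, ang = 0.03),
      cohorts = list(
        list(label = "EUR", proportions = c(1, 0, 0), n = 8),
        list(label = "GOG", proportions = c(0, 1, 0), n = 8),
        list(label = "ANG", proportions = c(0, 0, 1), n = 8),
        list(label = "ISL", proportions = c(0.10, 0.55, 0.35), n = 8))),
    qc = list(max_missing = 0.15, kin_threshold = 0.177),
    painting = list(n_hap_sites = 600, switch_rate = 5e-3, mis_copy = 1e-3),
    diversity = list(downsample_to = 5, reps = 3),
    uniparental = list(founder = rep(14L, 10), generations = 17,
                       mu = 0.0025, n_lineages = 25),
    social = list(d = 0.05, b = 3, tau = 1, T = 17))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  utils::modifyList(base, config)
}

manifest_add <- function(manifest, stage, path) {
  manifest$files[[length(manifest$files) + 1]] <- list(
    stage = stage, path = path, md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the full synthetic-data pipeline
#'
#' Runs the enabled stages in dependency order, writing each stage's
#' outputs (VCF, TSV, JSON) under the configured output directory and
#' recording every file with its checksum in a manifest. Rerunning with
#' the same configuration is bit-identical for the deterministic stages.
#' The ancestry stage requires the painting stage.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file of overrides.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_of <- function(stage) derive_seed(cfg$master_seed, stage)
  manifest <- list(package_version = as.character(utils::packageVersion("maroongen")),
                   master_seed = cfg$master_seed,
                   seeds = list(), files = list(), results = list())
  on_fail <- function(stage, e) {
    manifest$failed <<- list(stage = stage, message = conditionMessage(e))
    path <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  g <- NULL
  if (isTRUE(cfg$stages$simdata)) {
    manifest$seeds$simdata <- seed_of("simdata")
    tryCatch({
      sf <- sample_source_frequencies(cfg$simdata$n_sites, cfg$simdata$fst,
                                      seed = seed_of("simdata"))
      specs <- lapply(cfg$simdata$cohorts, function(cc)
        admixture_spec(cc$label, cc$proportions, cc$n))
      g <- simulate_admixed_genotypes(sf, specs, seed = seed_of("simdata"))
      vcf <- file.path(cfg$out_dir, "genotypes.vcf.gz")
      write_vcf(g, vcf)
      popf <- file.path(cfg$out_dir, "populations.tsv")
      write_pop_map(g, popf)
      manifest <- manifest_add(manifest, "simdata", vcf)
      manifest <- manifest_add(manifest, "simdata", popf)
    }, error = function(e) on_fail("simdata", e))
  }

  if (isTRUE(cfg$stages$qc)) {
    if (is.null(g)) on_fail("qc", simpleError("qc requires the simdata stage"))
    tryCatch({
      fr <- filter_sites(g, max_missing = cfg$qc$max_missing)
      pr <- prune_relatives(fr$genotypes, threshold = cfg$qc$kin_threshold)
      g <- pr$genotypes
      rep_path <- file.path(cfg$out_dir, "qc_report.json")
      write_filter_report(fr$report, rep_path)
      manifest <- manifest_add(manifest, "qc", rep_path)
      manifest$results$qc <- list(surviving_sites = fr$report$surviving,
                                  titv = fr$report$titv,
                                  removed_samples = pr$removed)
    }, error = function(e) on_fail("qc", e))
  }

  if (isTRUE(cfg$stages$structure)) {
    if (is.null(g)) on_fail("structure", simpleError("structure requires genotypes"))
    tryCatch({
      fm <- fst_matrix(g)
      fst_path <- file.path(cfg$out_dir, "fst_matrix.tsv")
      utils::write.table(fm, fst_path, sep = "\t", quote = FALSE, col.names = NA)
      pc <- pca(g, n_components = 4)
      pca_path <- file.path(cfg$out_dir, "pca_coordinates.tsv")
      utils::write.table(pc$coordinates, pca_path, sep = "\t", quote = FALSE,
                         col.names = NA)
      manifest <- manifest_add(manifest, "structure", fst_path)
      manifest <- manifest_add(manifest, "structure", pca_path)
      manifest$results$structure <-
        list(fst = if (all(c("GOG", "ANG") %in% rownames(fm)))
          fm["GOG", "ANG"] else NA)
    }, error = function(e) on_fail("structure", e))
  }

  cm <- NULL
  if (isTRUE(cfg$stages$painting)) {
    manifest$seeds$painting <- seed_of("painting")
    tryCatch({
      pcfg <- cfg$painting
      panel <- pipeline_hap_panel(pcfg, seed_of("painting"))
      cm <- coancestry(panel, mode = "donor_recipient",
                       donor_set = c("gog_don", "ang_don"),
                       recipient_set = c("ISL", "YRI_role", "GAN_role", "NYK_role"),
                       params = copying_params(pcfg$switch_rate, pcfg$mis_copy))
      cm_path <- file.path(cfg$out_dir, "coancestry.tsv")
      write_coancestry(cm, cm_path)
      manifest <- manifest_add(manifest, "painting", cm_path)
    }, error = function(e) on_fail("painting", e))
  }

  if (isTRUE(cfg$stages$ancestry)) {
    if (is.null(cm))
      on_fail("ancestry", simpleError("ancestry requires the painting stage"))
    tryCatch({
      prof <- cm$chunk_counts / rowSums(cm$chunk_counts)
      tree <- bootstrap_support(prof, cm$recipient_pops, n_reps = 100,
                                seed = seed_of("ancestry"))
      tree_path <- file.path(cfg$out_dir, "tvd_nj_tree.nwk")
      ape::write.tree(tree, tree_path)
      est <- nj_geometry_ancestry(tree, "ISL", "YRI_role",
                                  c("GAN_role", "NYK_role"))
      est_path <- file.path(cfg$out_dir, "ancestry_estimates.tsv")
      utils::write.table(est, est_path, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- manifest_add(manifest, "ancestry", tree_path)
      manifest <- manifest_add(manifest, "ancestry", est_path)
      manifest$results$ancestry <- list(
        isl_gog = est$proportion[est$source == "gulf_of_guinea"])
    }, error = function(e) on_fail("ancestry", e))
  }

  if (isTRUE(cfg$stages$diversity)) {
    if (is.null(g)) on_fail("diversity", simpleError("diversity requires genotypes"))
    manifest$seeds$diversity <- seed_of("diversity")
    tryCatch({
      hs <- het_stats(g)
      het_path <- file.path(cfg$out_dir, "het_stats.tsv")
      utils::write.table(hs, het_path, sep = "\t", quote = FALSE, row.names = FALSE)
      tab <- table(g$samples$pop)
      sfs_pop <- names(tab)[which.max(tab)]
      sfs <- folded_sfs(g, sfs_pop, downsample_to = cfg$diversity$downsample_to,
                        reps = cfg$diversity$reps, seed = seed_of("diversity"))
      sfs_path <- file.path(cfg$out_dir, paste0("sfs_", sfs_pop, ".tsv"))
      utils::write.table(data.frame(maf = seq_along(sfs), proportion = sfs),
                         sfs_path, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- manifest_add(manifest, "diversity", het_path)
      manifest <- manifest_add(manifest, "diversity", sfs_path)
    }, error = function(e) on_fail("diversity", e))
  }

  if (isTRUE(cfg$stages$uniparental)) {
    manifest$seeds$uniparental <- seed_of("uniparental")
    tryCatch({
      ucfg <- cfg$uniparental
      ys <- simulate_ystr("star", ucfg$founder, ucfg$generations, ucfg$mu,
                          ucfg$n_lineages, seed = seed_of("uniparental"))
      ystr_path <- file.path(cfg$out_dir, "ystr.tsv")
      write_ystr(ys, ystr_path)
      modal <- modal_haplotype(ys, "star")
      cl <- delimit_descent_cluster(ys, modal$haplotype)
      tm <- rho_tmrca(cl, mu = ucfg$mu, n_loci = length(ucfg$founder))
      tm_path <- file.path(cfg$out_dir, "tmrca.json")
      jsonlite::write_json(unclass(tm), tm_path, auto_unbox = TRUE, digits = NA)
      manifest <- manifest_add(manifest, "uniparental", ystr_path)
      manifest <- manifest_add(manifest, "uniparental", tm_path)
      manifest$results$uniparental <- list(tmrca_years = tm$years)
    }, error = function(e) on_fail("uniparental", e))
  }

  if (isTRUE(cfg$stages$social)) {
    tryCatch({
      scfg <- cfg$social
      m <- dominance_model(scfg$d, scfg$b, scfg$tau)
      traj <- trajectory(m, scfg$T)
      traj_path <- file.path(cfg$out_dir, "social_trajectory.tsv")
      utils::write.table(traj, traj_path, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- manifest_add(manifest, "social", traj_path)
      manifest$results$social <- list(final_p = utils::tail(traj$p, 1))
    }, error = function(e) on_fail("social", e))
  }

  path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# small phased panel for the painting/ancestry stages: donor populations
# with distinct haplotype pools, recipients simulated as mosaics
pipeline_hap_panel <- function(pcfg, seed) {
  S <- pcfg$n_hap_sites
  with_seed(seed, {
    sites <- data.frame(chrom = "1", pos = seq_len(S) * 1000,
                        ref = "A", alt = "G")
    freq_g <- stats::runif(S, 0.05, 0.95)
    freq_a <- clamp01(freq_g + stats::rnorm(S, 0, 0.25))
    draw <- function(f, n) t(vapply(seq_len(n), function(i)
      stats::rbinom(S, 1, f), numeric(S)))
    don_g <- draw(freq_g, 8); don_a <- draw(freq_a, 8)
    mk_rec <- function(alpha, n, seed2) {
      simulate_haplotype_mosaic(list(gog = don_g, ang = don_a),
                                c(alpha, 1 - alpha), pcfg$switch_rate, n,
                                seed = seed2)$haps
    }
    rec_isl <- mk_rec(0.58, 8, derive_seed(seed, "isl"))
    rec_yri <- mk_rec(1 - 1e-9, 4, derive_seed(seed, "yri"))
    rec_gan <- mk_rec(1e-9, 4, derive_seed(seed, "gan"))
    rec_nyk <- mk_rec(1e-9, 4, derive_seed(seed, "nyk"))
    haps <- rbind(don_g, don_a, rec_isl, rec_yri, rec_gan, rec_nyk)
    ind <- c(sprintf("dg_%d", rep(1:4, each = 2)), sprintf("da_%d", rep(1:4, each = 2)),
             sprintf("isl_%d", rep(1:4, each = 2)), sprintf("yri_%d", rep(1:2, each = 2)),
             sprintf("gan_%d", rep(1:2, each = 2)), sprintf("nyk_%d", rep(1:2, each = 2)))
    pop <- c(rep("gog_don", 8), rep("ang_don", 8), rep("ISL", 8),
             rep("YRI_role", 4), rep("GAN_role", 4), rep("NYK_role", 4))
    hap_panel(haps, sites, ind, pop)
  })
}
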