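# Y-STR and mtDNA analyses: modal haplotypes, descent-cluster delimitation,
# rho-statistic TMRCA, match-profile summaries and molecular diversity
# indices.

hap_key <- function(m) apply(m, 1, paste, collapse = "-")

# stepwise mutational distance: sum over loci of |repeat difference|
ystr_distance <- function(a, b) sum(abs(a - b))

#' Modal (most frequent) Y-STR haplotype in a population
#'
#' Ties are broken deterministically: larger total repeat sum first, then
#' lexicographically smaller haplotype key, so the winner does not depend
#' on input order.
#'
#' @param data A `ystr_dataset`.
#' @param pop Population label.
#' @param loci_mask Optional locus names to use (e.g. excluding a
#'   duplicated locus).
#' @return List with `haplotype` (integer vector), `count`, `frequency`.
#' @export
modal_haplotype <- function(data, pop, loci_mask = NULL) {
  rows <- which(data$labels == pop)
  if (length(rows) == 0) stop_param("no haplotypes in population %s", pop)
  loci <- loci_mask %||% data$loci
  m <- data$haplotypes[rows, loci, drop = FALSE]
  keys <- hap_key(m)
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    sums <- vapply(top, function(k) sum(m[match(k, keys), ]), numeric(1))
    top <- top[order(-sums, top)]
  }
  win <- m[match(top[1], keys), ]
  list(haplotype = stats::setNames(as.integer(win), loci),
       count = as.integer(max(tab)),
       frequency = as.numeric(max(tab)) / length(rows))
}

#' Delimit a descent cluster around an ancestral haplotype
#'
#' Breadth-first growth from the ancestral haplotype over the sampled
#' haplotypes: a haplotype joins the cluster if it differs from a current
#' member at exactly one locus by at most `max_step` repeat units. Chains
#' of sampled single-step neighbors are therefore included even when their
#' total distance to the ancestral haplotype exceeds one. Multiplicities
#' are preserved. The result is independent of haplotype input order.
#'
#' @param data A `ystr_dataset`.
#' @param ancestral Ancestral (modal) haplotype, over `loci_mask` loci.
#' @param max_step Maximum repeat difference per connecting edge.
#' @param loci_mask Optional locus names to use.
#' @return A `descent_cluster`: `ancestral`, `members` (matrix with one row
#'   per sampled copy), `distances` (stepwise distance to the ancestral
#'   haplotype per copy), `n`.
#' @export
delimit_descent_cluster <- function(data, ancestral, max_step = 1,
                                    loci_mask = NULL) {
  loci <- loci_mask %||% data$loci
  m <- data$haplotypes[, loci, drop = FALSE]
  anc <- if (is.null(names(ancestral))) as.integer(ancestral)
         else as.integer(ancestral[loci])
  if (length(anc) != length(loci) || any(is.na(anc)))
    stop_param("ancestral haplotype does not cover the requested loci")
  keys <- hap_key(m)
  uniq <- unique(keys)
  anc_key <- paste(anc, collapse = "-")
  if (!anc_key %in% uniq) stop_param("ancestral haplotype absent from data")
  umat <- m[match(uniq, keys), , drop = FALSE]
  one_step <- function(a, b) {
    dd <- abs(a - b)
    sum(dd > 0) == 1 && max(dd) <= max_step
  }
  in_cluster <- uniq == anc_key
  frontier <- which(in_cluster)
  while (length(frontier) > 0) {
    new_frontier <- integer(0)
    for (f in frontier) {
      for (u in which(!in_cluster)) {
        if (one_step(umat[f, ], umat[u, ])) {
          in_cluster[u] <- TRUE
          new_frontier <- c(new_frontier, u)
        }
      }
    }
    frontier <- new_frontier
  }
  member_rows <- which(keys %in% uniq[in_cluster])
  members <- m[member_rows, , drop = FALSE]
  distances <- apply(members, 1, ystr_distance, b = anc)
  structure(list(ancestral = stats::setNames(anc, loci), members = members,
                 distances = unname(distances), n = length(member_rows)),
            class = "descent_cluster")
}

#' rho-statistic TMRCA of a descent cluster
#'
#' `rho` is the mean stepwise mutational distance of cluster members (with
#' multiplicity) to the ancestral haplotype; the age in generations is
#' `rho / (n_loci * mu)`, converted to years by the generation time. The
#' standard error uses the star-genealogy approximation
#' `sqrt(rho / n) / (n_loci * mu)` generations, giving a normal 95%
#' interval floored at zero. When `rho = 0` the upper limit substitutes the
#' exact Poisson 97.5% bound for zero observed mutations.
#'
#' @param cluster A `descent_cluster`, or a numeric vector of mutational
#'   distances.
#' @param mu Mutation rate per locus per generation.
#' @param n_loci Number of loci over which distances were computed.
#' @param gen_time Generation time in years.
#' @return A `tmrca_estimate`: `rho`, `n_lineages`, `generations`, `years`,
#'   `ci_years`, plus the parameters.
#' @export
rho_tmrca <- function(cluster, mu = 0.0025, n_loci = 10, gen_time = 30) {
  if (mu <= 0 || gen_time <= 0) stop_param("mu and gen_time must be positive")
  dists <- if (inherits(cluster, "descent_cluster")) cluster$distances else as.numeric(cluster)
  n <- length(dists)
  if (n == 0) stop_param("empty cluster")
  rho <- mean(dists)
  gens <- rho / (n_loci * mu)
  years <- gens * gen_time
  if (rho > 0) {
    se_gen <- sqrt(rho / n) / (n_loci * mu)
    ci <- c(max(0, years - 1.96 * se_gen * gen_time),
            years + 1.96 * se_gen * gen_time)
  } else {
    upper_total <- stats::qchisq(0.975, 2) / 2  # exact Poisson bound, 0 counts
    ci <- c(0, (upper_total / n) / (n_loci * mu) * gen_time)
  }
  structure(list(rho = rho, n_lineages = n, generations = gens, years = years,
                 ci_years = ci, mu = mu, n_loci = n_loci, gen_time = gen_time),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("rho = %.3f over %d lineages -> %.1f generations = %.0f years (95%% CI %.0f-%.0f)\n",
              x$rho, x$n_lineages, x$generations, x$years,
              x$ci_years[1], x$ci_years[2]))
  invisible(x)
}

#' Haplotype match-profile summary
#'
#' Summarizes a table of haplotype matches against reference populations:
#' the focal region's share of matches, its share of the total sample size,
#' and the representation ratio (match share / size share; 1 means matches
#' proportional to sampling).
#'
#' @param table `data.frame` with columns `population` (or any id),
#'   `region`, `n_matches`, `sample_size`.
#' @param focal_region Region of interest.
#' @return List with `match_share`, `size_share`, `representation_ratio`,
#'   `focal_matches`, `total_matches`, `focal_size`, `total_size`.
#' @export
match_profile <- function(table, focal_region) {
  if (nrow(table) == 0) stop_param("empty match table")
  if (!focal_region %in% table$region) stop_param("region %s absent", focal_region)
  if (any(table$n_matches < 0) || any(table$n_matches != round(table$n_matches)))
    stop_param("match counts must be nonnegative integers")
  tm <- sum(table$n_matches); ts <- sum(table$sample_size)
  fm <- sum(table$n_matches[table$region == focal_region])
  fs <- sum(table$sample_size[table$region == focal_region])
  if (tm == 0) {
    warning("zero total matches; shares undefined")
    return(list(match_share = NA_real_, size_share = fs / ts,
                representation_ratio = NA_real_,
                focal_matches = fm, total_matches = tm,
                focal_size = fs, total_size = ts))
  }
  ms <- fm / tm; ss <- fs / ts
  list(match_share = ms, size_share = ss, representation_ratio = ms / ss,
       focal_matches = fm, total_matches = tm, focal_size = fs, total_size = ts)
}

#' Molecular diversity indices for aligned sequences
#'
#' Haplotype diversity `H = n (1 - sum p_i^2) / (n - 1)` and nucleotide
#' diversity (mean pairwise difference per site, gaps and Ns excluded
#' pairwise), with the haplotype and segregating-site counts.
#'
#' @param seqs Character vector of equal-length aligned sequences.
#' @return List with `haplotype_diversity`, `nucleotide_diversity`,
#'   `n_haplotypes`, `segregating_sites`, `n`.
#' @export
seq_diversity <- function(seqs) {
  n <- length(seqs)
  if (n < 2) stop_param("need at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop_param("sequences must be aligned (equal length)")
  m <- toupper(do.call(rbind, strsplit(seqs, "")))
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  p <- as.numeric(table(apply(m, 1, paste, collapse = ""))) / n
  H <- n * (1 - sum(p^2)) / (n - 1)
  pair_pi <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok)) next
    pair_pi <- c(pair_pi, sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  seg <- sum(apply(m, 2, function(col) {
    cc <- col[col %in% c("A", "C", "G", "T")]
    length(unique(cc)) > 1
  }))
  list(haplotype_diversity = H, nucleotide_diversity = mean(pair_pi),
       n_haplotypes = length(p), segregating_sites = seg, n = n)
}
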