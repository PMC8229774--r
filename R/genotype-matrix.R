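#' Genotype matrix container
#'
#' Diploid genotypes for a set of individuals at autosomal biallelic SNPs,
#' stored as a dosage matrix (count of alternate alleles, 0/1/2, `NA` for
#' missing) with per-genotype depth and quality when available.
#'
#' @param dosage Integer matrix, samples in rows, sites in columns; entries
#'   0, 1, 2 or `NA`.
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`. Positions must be strictly increasing within a chromosome.
#' @param samples `data.frame` with columns `id` and `pop` (population label).
#' @param depth Optional integer matrix of per-genotype sequencing depth,
#'   same shape as `dosage`.
#' @param qual Optional integer matrix of per-genotype qualities (GQ).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, samples, depth = NULL, qual = NULL) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(samples))
    stop_param("dosage has %d rows but %d samples given", nrow(dosage), nrow(samples))
  if (ncol(dosage) != nrow(sites))
    stop_param("dosage has %d columns but %d sites given", ncol(dosage), nrow(sites))
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop_param("dosage entries must be 0, 1, 2 or NA")
  if (any(sites$ref == sites$alt)) stop_param("ref and alt alleles must differ")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop_param("positions must be strictly increasing within chromosome %s", ch)
  }
  rownames(dosage) <- samples$id
  g <- list(dosage = dosage, sites = as.data.frame(sites),
            samples = as.data.frame(samples), depth = depth, qual = qual)
  class(g) <- "genotype_matrix"
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%d populations)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$samples$pop))))
  cat(sprintf("  missing: %.2f%%; depth/qual: %s/%s\n",
              100 * mean(is.na(x$dosage)),
              if (is.null(x$depth)) "no" else "yes",
              if (is.null(x$qual)) "no" else "yes"))
  invisible(x)
}

n_samples <- function(g) nrow(g$dosage)
n_sites <- function(g) ncol(g$dosage)

subset_sites <- function(g, keep) {
  genotype_matrix(g$dosage[, keep, drop = FALSE], g$sites[keep, , drop = FALSE],
                  g$samples,
                  depth = if (!is.null(g$depth)) g$depth[, keep, drop = FALSE],
                  qual = if (!is.null(g$qual)) g$qual[, keep, drop = FALSE])
}

subset_samples <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$samples$id)
  genotype_matrix(g$dosage[keep, , drop = FALSE], g$sites,
                  g$samples[keep, , drop = FALSE],
                  depth = if (!is.null(g$depth)) g$depth[keep, , drop = FALSE],
                  qual = if (!is.null(g$qual)) g$qual[keep, , drop = FALSE])
}

# Per-site alternate allele frequency for one population (or all samples).
allele_freq <- function(g, pop = NULL) {
  d <- g$dosage
  if (!is.null(pop)) d <- d[g$samples$pop %in% pop, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Phased haplotype panel
#'
#' Haplotypes as a 0/1 matrix (two rows per diploid individual) over a
#' shared site list, with individual ids and population labels.
#'
#' @param haps 0/1 matrix, haplotypes in rows.
#' @param sites Site `data.frame` as in [genotype_matrix()].
#' @param individual Individual id per haplotype row.
#' @param pop Population label per haplotype row.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haps, sites, individual, pop) {
  haps <- as.matrix(haps)
  stopifnot(nrow(haps) == length(individual), length(individual) == length(pop),
            ncol(haps) == nrow(sites))
  if (any(!haps %in% 0:1)) stop_param("haplotype entries must be 0/1")
  structure(list(haps = haps, sites = as.data.frame(sites),
                 individual = as.character(individual), pop = as.character(pop)),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d haplotypes (%d individuals) x %d sites\n",
              nrow(x$haps), length(unique(x$individual)), ncol(x$haps)))
  invisible(x)
}

# ---- VCF input/output (via vcfR) -------------------------------------------

#' @importClassesFrom vcfR vcfR
NULL

#' Write genotypes to VCF 4.2
#'
#' Writes a `genotype_matrix` (unphased `/` genotypes, with DP and GQ FORMAT
#' fields when present) or a `hap_panel` (phased `|` genotypes). Output is
#' bgzip-compressed as produced by [vcfR::write.vcf()]; use a `.vcf.gz` path.
#'
#' @param x A `genotype_matrix` or `hap_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "hap_panel")) {
    sites <- x$sites
    ids <- unique(x$individual)
    gt_body <- sapply(ids, function(id) {
      rows <- which(x$individual == id)
      if (length(rows) != 2) stop_param("individual %s does not have 2 haplotypes", id)
      paste0(x$haps[rows[1], ], "|", x$haps[rows[2], ])
    })
    fmt <- "GT"
  } else {
    sites <- x$sites
    ids <- x$samples$id
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt_chr <- matrix("./.", nrow = nrow(x$dosage), ncol = ncol(x$dosage))
    ok <- !is.na(x$dosage)
    gt_chr[ok] <- code[as.character(x$dosage[ok])]
    fmt <- "GT"
    if (!is.null(x$depth)) {
      gt_chr <- matrix(paste0(gt_chr, ":", ifelse(is.na(x$depth), ".", x$depth)),
                       nrow = nrow(gt_chr))
      fmt <- paste0(fmt, ":DP")
    }
    if (!is.null(x$qual)) {
      gt_chr <- matrix(paste0(gt_chr, ":", ifelse(is.na(x$qual), ".", x$qual)),
                       nrow = nrow(gt_chr))
      fmt <- paste0(fmt, ":GQ")
    }
    gt_body <- t(gt_chr)
    colnames(gt_body) <- ids
  }
  fix <- cbind(CHROM = as.character(sites$chrom), POS = as.character(sites$pos),
               ID = paste0("s", seq_len(nrow(sites))), REF = as.character(sites$ref),
               ALT = as.character(sites$alt), QUAL = ".", FILTER = "PASS", INFO = ".")
  gt <- cbind(FORMAT = fmt, gt_body)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @param pops Optional named vector or population-map `data.frame`
#'   (`sample_id`, `population`) assigning samples to populations.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, pops = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(s) {
    a <- strsplit(gsub("\\|", "/", s), "/", fixed = TRUE)
    vapply(a, function(z) {
      if (length(z) != 2 || any(z == ".")) return(NA_integer_)
      sum(as.integer(z))
    }, integer(1))
  }
  dos <- t(matrix(alt_count(as.vector(gt)), nrow = nrow(gt)))  # samples x sites
  ids <- colnames(gt)
  sites <- data.frame(chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                      ref = vcfR::getREF(v), alt = vcfR::getALT(v))
  dp <- tryCatch(suppressWarnings(t(vcfR::extract.gt(v, "DP", as.numeric = TRUE))),
                 error = function(e) NULL)
  gq <- tryCatch(suppressWarnings(t(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))),
                 error = function(e) NULL)
  pop <- rep("pop1", length(ids))
  if (!is.null(pops)) {
    if (is.data.frame(pops)) pops <- stats::setNames(pops[[2]], pops[[1]])
    pop <- unname(pops[ids])
  }
  genotype_matrix(dos, sites, data.frame(id = ids, pop = pop),
                  depth = dp, qual = gq)
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires `|`-phased GT fields with no missing genotypes.
#' @inheritParams read_vcf
#' @return A `hap_panel`.
#' @export
read_phased_vcf <- function(path, pops = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gt, fixed = TRUE)))
    stop_param("unphased genotypes in %s", path)
  ids <- colnames(gt)
  h1 <- apply(gt, 2, function(s) as.integer(substr(s, 1, 1)))
  h2 <- apply(gt, 2, function(s) as.integer(substr(s, 3, 3)))
  haps <- matrix(0L, nrow = 2 * length(ids), ncol = nrow(gt))
  haps[seq(1, 2 * length(ids), by = 2), ] <- t(h1)
  haps[seq(2, 2 * length(ids), by = 2), ] <- t(h2)
  sites <- data.frame(chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                      ref = vcfR::getREF(v), alt = vcfR::getALT(v))
  pop <- rep("pop1", length(ids))
  if (!is.null(pops)) {
    if (is.data.frame(pops)) pops <- stats::setNames(pops[[2]], pops[[1]])
    pop <- unname(pops[ids])
  }
  hap_panel(haps, sites, rep(ids, each = 2), rep(pop, each = 2))
}

#' Write / read a sample-to-population map (TSV)
#' @param g A `genotype_matrix`, `hap_panel`, or `data.frame` with `id`, `pop`.
#' @param path TSV path.
#' @return `path` invisibly; `read_pop_map` returns a `data.frame`.
#' @export
write_pop_map <- function(g, path) {
  df <- if (inherits(g, "genotype_matrix")) {
    data.frame(sample_id = g$samples$id, population = g$samples$pop)
  } else if (inherits(g, "hap_panel")) {
    keep <- !duplicated(g$individual)
    data.frame(sample_id = g$individual[keep], population = g$pop[keep])
  } else data.frame(sample_id = g$id, population = g$pop)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pop_map
#' @export
read_pop_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
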