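# Site and genotype quality control, Hardy-Weinberg filtering, Ti/Tv and
# KING-robust kinship pruning.

new_filter_report <- function(rules, surviving, titv = NA_real_) {
  structure(list(rules = rules, surviving = surviving, titv = titv),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  for (nm in names(x$rules)) cat(sprintf("  %-24s removed %d\n", nm, x$rules[[nm]]))
  cat(sprintf("  surviving sites: %d (Ti/Tv %.3f)\n", x$surviving, x$titv))
  invisible(x)
}

#' Write a filter report to JSON
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Site and genotype filters
#'
#' Applies, in fixed order: (1) removal of non-autosomal and non-biallelic-SNP
#' sites; (2) removal of sites whose mean genotype depth is at or above
#' `max_mean_depth`; (3) masking (set to missing) of genotypes below the
#' depth or quality thresholds; (4) removal of sites whose post-masking
#' missing fraction exceeds `max_missing`. Masking precedes the missingness
#' rule, so low-quality genotypes count as missing. The function is
#' idempotent: re-applying it to its own output removes nothing.
#'
#' @param g A `genotype_matrix`.
#' @param max_mean_depth Remove sites with mean depth >= this (x coverage).
#' @param min_geno_depth Mask genotypes with depth below this.
#' @param min_geno_qual Mask genotypes with quality below this.
#' @param max_missing Remove sites with missing fraction > this.
#' @return `list(genotypes, report)`.
#' @export
filter_sites <- function(g, max_mean_depth = 35, min_geno_depth = 3,
                         min_geno_qual = 20, max_missing = 0.15) {
  if (max_mean_depth < 0 || min_geno_depth < 0 || min_geno_qual < 0 || max_missing < 0)
    stop_param("thresholds must be nonnegative")
  rules <- c()
  biallelic <- nchar(as.character(g$sites$ref)) == 1 &
    nchar(as.character(g$sites$alt)) == 1 &
    !grepl(",", g$sites$alt, fixed = TRUE)
  auto <- is_autosome(g$sites$chrom)
  keep1 <- biallelic & auto
  rules["non_autosomal_or_multiallelic"] <- sum(!keep1)
  g <- subset_sites(g, keep1)

  if (!is.null(g$depth)) {
    mean_dp <- colMeans(g$depth, na.rm = TRUE)
    keep2 <- is.na(mean_dp) | mean_dp < max_mean_depth
    rules["excess_mean_depth"] <- sum(!keep2)
    g <- subset_sites(g, keep2)
  } else rules["excess_mean_depth"] <- 0L

  masked <- 0L
  if (!is.null(g$depth)) {
    low <- !is.na(g$depth) & g$depth < min_geno_depth & !is.na(g$dosage)
    masked <- masked + sum(low)
    g$dosage[low] <- NA_integer_
  }
  if (!is.null(g$qual)) {
    low <- !is.na(g$qual) & g$qual < min_geno_qual & !is.na(g$dosage)
    masked <- masked + sum(low)
    g$dosage[low] <- NA_integer_
  }
  rules["genotypes_masked"] <- masked

  miss <- colMeans(is.na(g$dosage))
  keep3 <- miss <= max_missing
  rules["excess_missingness"] <- sum(!keep3)
  g <- subset_sites(g, keep3)

  report <- new_filter_report(as.list(rules), n_sites(g), ti_tv(g))
  list(genotypes = g, report = report)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the allele counts: the p-value is the
#' summed probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed configuration.
#' Monomorphic sites return p = 1 by convention (nothing to reject).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_param("counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_param("need at least one genotype")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)   # feasible heterozygote counts
  # log P(n_Aa = h | nA, na) up to a shared constant
  logp <- vapply(hets, function(h) {
    hom1 <- (nA - h) / 2; hom2 <- (na - h) / 2
    h * log(2) - lfactorial(hom1) - lfactorial(h) - lfactorial(hom2)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Hardy-Weinberg site filter across populations
#'
#' A site is removed iff its per-population exact test p-value is below
#' `alpha` in at least `min_pops` populations.
#'
#' @param g A `genotype_matrix` (population labels taken from `g$samples$pop`).
#' @param alpha Significance level.
#' @param min_pops Minimum number of failing populations for removal.
#' @return `list(genotypes, report, p_values)` where `p_values` is a
#'   populations x sites matrix.
#' @export
hwe_filter <- function(g, alpha = 0.05, min_pops = 2) {
  pops <- unique(g$samples$pop)
  sizes <- vapply(pops, function(p) sum(g$samples$pop == p), integer(1))
  usable <- pops[sizes >= 2]
  if (length(usable) < min_pops)
    warning("fewer than min_pops populations with >= 2 individuals; no site can fail")
  pv <- matrix(1, nrow = length(usable), ncol = n_sites(g),
               dimnames = list(usable, NULL))
  for (p in usable) {
    d <- g$dosage[g$samples$pop == p, , drop = FALSE]
    nAA <- colSums(d == 0, na.rm = TRUE)
    nAa <- colSums(d == 1, na.rm = TRUE)
    naa <- colSums(d == 2, na.rm = TRUE)
    pv[p, ] <- vapply(seq_len(ncol(d)), function(s) {
      if (nAA[s] + nAa[s] + naa[s] < 1) return(1)
      hwe_exact_test(nAA[s], nAa[s], naa[s])
    }, numeric(1))
  }
  fails <- colSums(pv < alpha)
  keep <- fails < min_pops
  report <- new_filter_report(list(hwe_failed = sum(!keep)), sum(keep))
  g2 <- subset_sites(g, keep)
  report$titv <- ti_tv(g2)
  list(genotypes = g2, report = report, p_values = pv)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else between single
#' nucleotides is a transversion. Returns `Inf` when there are transitions
#' but no transversions, and 0 when there are no transitions.
#'
#' @param g A `genotype_matrix`.
#' @return Ti/Tv ratio.
#' @export
ti_tv <- function(g) {
  pair <- paste0(toupper(g$sites$ref), toupper(g$sites$alt))
  ti <- pair %in% c("AG", "GA", "CT", "TC")
  n_ti <- sum(ti); n_tv <- sum(!ti)
  if (n_tv == 0) return(if (n_ti > 0) Inf else NaN)
  n_ti / n_tv
}

#' KING-robust kinship coefficient for one pair
#'
#' `phi = (N_AaAa - 2 * N_opp_hom) / (N_Aa(i) + N_Aa(j))` over jointly
#' non-missing sites, where `N_AaAa` counts sites heterozygous in both and
#' `N_opp_hom` counts opposite homozygotes. Self-comparison gives 0.5;
#' parent-offspring pairs are expected near 0.25; unrelated pairs near 0.
#'
#' @param g A `genotype_matrix`.
#' @param i,j Sample ids or row indices.
#' @return Kinship coefficient (scalar). `NA` with a warning if the
#'   denominator is zero.
#' @export
king_kinship <- function(g, i, j) {
  if (is.character(i)) i <- match(i, g$samples$id)
  if (is.character(j)) j <- match(j, g$samples$id)
  x <- g$dosage[i, ]; y <- g$dosage[j, ]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop_param("no jointly non-missing sites")
  x <- x[ok]; y <- y[ok]
  het_het <- sum(x == 1 & y == 1)
  opp_hom <- sum((x == 0 & y == 2) | (x == 2 & y == 0))
  den <- sum(x == 1) + sum(y == 1)
  if (den == 0) {
    warning("KING denominator zero (no heterozygous sites in either sample)")
    return(NA_real_)
  }
  (het_het - 2 * opp_hom) / den
}

#' Pairwise KING kinship matrix
#' @param g A `genotype_matrix`.
#' @return Symmetric matrix of kinship coefficients (diagonal 0.5).
#' @export
kinship_matrix <- function(g) {
  n <- n_samples(g)
  phi <- matrix(0, n, n, dimnames = list(g$samples$id, g$samples$id))
  for (i in seq_len(n)) {
    phi[i, i] <- 0.5
    for (j in seq_len(n)[-seq_len(i)]) {
      phi[i, j] <- phi[j, i] <- king_kinship(g, i, j)
    }
  }
  phi
}

#' Greedy relatedness pruning
#'
#' While any pair exceeds the kinship threshold, removes the member involved
#' in more such pairs; ties are broken by higher missingness, then
#' lexicographically smaller id. The default threshold 0.177 is the
#' conventional boundary between first- and second-degree relatives.
#'
#' @param g A `genotype_matrix`.
#' @param threshold Kinship threshold.
#' @return `list(genotypes, removed)`.
#' @export
prune_relatives <- function(g, threshold = 0.177) {
  phi <- kinship_matrix(g)
  diag(phi) <- 0
  active <- rep(TRUE, n_samples(g))
  names(active) <- g$samples$id
  miss <- rowMeans(is.na(g$dosage))
  removed <- character(0)
  repeat {
    m <- phi
    m[!active, ] <- 0; m[, !active] <- 0
    deg <- rowSums(m > threshold)
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    if (length(worst) > 1) {
      worst <- worst[order(-miss[worst], g$samples$id[worst])]
    }
    drop_i <- worst[1]
    active[drop_i] <- FALSE
    removed <- c(removed, g$samples$id[drop_i])
  }
  list(genotypes = subset_samples(g, which(active)), removed = removed)
}
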