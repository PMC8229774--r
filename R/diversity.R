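# Genome-wide diversity statistics: runs of homozygosity (PLINK-style
# two-pass scan), LD decay binning, folded site frequency spectra with
# individual downsampling, observed heterozygosity and inbreeding
# coefficients.

#' Call runs of homozygosity (PLINK-style two-pass scan)
#'
#' Pass 1 slides windows of `win_snp` SNPs (windows are truncated, not
#' dropped, at chromosome ends); a window is homozygous if it contains at
#' most `win_het` heterozygous and `win_missing` missing calls. A SNP is
#' eligible if the fraction of overlapping windows that are homozygous is
#' at least `win_threshold`. Pass 2 emits maximal runs of eligible SNPs,
#' split at inter-SNP gaps above `gap_kb`, that satisfy the minimum SNP
#' count, minimum length, and SNP density conditions.
#'
#' @param g A `genotype_matrix` with sites sorted by position.
#' @param density_kb Maximum average kb per SNP inside a run.
#' @param gap_kb Maximum allowed gap (kb) between consecutive run SNPs.
#' @param min_kb Minimum run length (kb).
#' @param min_snp Minimum number of SNPs in a run.
#' @param win_het Maximum heterozygous calls per homozygous window.
#' @param win_missing Maximum missing calls per homozygous window.
#' @param win_snp Window size in SNPs.
#' @param win_threshold Minimum homozygous-window fraction for eligibility.
#' @return `data.frame(sample, chrom, start, end, n_snps, length_kb)`.
#' @export
call_roh <- function(g, density_kb = 50, gap_kb = 500, min_kb = 500,
                     min_snp = 100, win_het = 1, win_missing = 5,
                     win_snp = 50, win_threshold = 0.05) {
  segs <- list()
  for (ch in unique(g$sites$chrom)) {
    cols <- which(g$sites$chrom == ch)
    pos <- g$sites$pos[cols]
    if (is.unsorted(pos, strictly = TRUE)) stop_param("unsorted positions on %s", ch)
    S <- length(cols)
    for (si in seq_len(n_samples(g))) {
      x <- g$dosage[si, cols]
      het <- as.numeric(!is.na(x) & x == 1)
      mis <- as.numeric(is.na(x))
      # windows start at every SNP and are truncated at the right end
      ends <- pmin(seq_len(S) + win_snp - 1, S)
      cs_het <- c(0, cumsum(het)); cs_mis <- c(0, cumsum(mis))
      w_het <- cs_het[ends + 1] - cs_het[seq_len(S)]
      w_mis <- cs_mis[ends + 1] - cs_mis[seq_len(S)]
      hom_win <- as.numeric(w_het <= win_het & w_mis <= win_missing)
      # SNP j is overlapped by windows starting in [j - win_snp + 1, j]
      cs_hom <- c(0, cumsum(hom_win))
      starts_lo <- pmax(seq_len(S) - win_snp + 1, 1)
      n_hom <- cs_hom[seq_len(S) + 1] - cs_hom[starts_lo]
      n_win <- seq_len(S) - starts_lo + 1
      eligible <- n_hom / n_win >= win_threshold
      # maximal eligible runs, split at large gaps
      r <- rle(eligible)
      run_ends <- cumsum(r$lengths)
      run_starts <- run_ends - r$lengths + 1
      for (k in which(r$values)) {
        idx <- run_starts[k]:run_ends[k]
        gaps <- which(diff(pos[idx]) > gap_kb * 1000)
        pieces <- split(idx, findInterval(seq_along(idx), gaps + 1))
        for (piece in pieces) {
          np <- length(piece)
          if (np < min_snp) next
          len_kb <- (pos[piece[np]] - pos[piece[1]] + 1) / 1000
          if (len_kb < min_kb) next
          if (len_kb / np > density_kb) next
          segs[[length(segs) + 1]] <- data.frame(
            sample = g$samples$id[si], chrom = ch,
            start = pos[piece[1]], end = pos[piece[np]],
            n_snps = np, length_kb = len_kb)
        }
      }
    }
  }
  if (length(segs) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), length_kb = numeric()))
  do.call(rbind, segs)
}

#' Per-sample ROH summary
#'
#' @param segments Output of [call_roh()].
#' @param sample_ids All sample ids (so samples without segments appear with
#'   zero counts).
#' @param class_breaks_kb Length-class breakpoints in kb; the last class is
#'   open-ended (`> 2 Mb` with the default breaks).
#' @return `data.frame(sample, nROH, sROH_kb, mean_kb, class counts...)`.
#' @export
roh_summary <- function(segments, sample_ids,
                        class_breaks_kb = c(500, 1000, 2000)) {
  cls_lab <- c(paste0("roh_", head_labels(class_breaks_kb)),
               sprintf("roh_gt_%dkb", class_breaks_kb[length(class_breaks_kb)]))
  out <- lapply(sample_ids, function(id) {
    s <- segments[segments$sample == id, , drop = FALSE]
    n <- nrow(s); tot <- sum(s$length_kb)
    cls <- table(cut(s$length_kb, c(class_breaks_kb, Inf), right = FALSE,
                     labels = cls_lab))
    cbind(data.frame(sample = id, nROH = n, sROH_kb = tot,
                     mean_kb = if (n > 0) tot / n else NA_real_),
          as.data.frame.matrix(t(as.matrix(cls))))
  })
  do.call(rbind, out)
}

head_labels <- function(breaks) {
  if (length(breaks) < 2) return(character(0))
  sprintf("%d_%dkb", breaks[-length(breaks)], breaks[-1])
}

#' Residuals of total ROH length on ROH count
#'
#' Fits an ordinary least squares line of `sROH` on `nROH` in a baseline
#' (outbred) sample set and reports residuals for all samples; a positive
#' residual means more total ROH than the count predicts, an inbreeding
#' signal.
#'
#' @param summaries Output of [roh_summary()].
#' @param baseline_samples Ids of baseline samples (>= 3, non-constant nROH).
#' @return `data.frame(sample, residual, baseline)`.
#' @export
roh_regression_residual <- function(summaries, baseline_samples) {
  base <- summaries[summaries$sample %in% baseline_samples, ]
  if (nrow(base) < 3) stop_param("need >= 3 baseline samples")
  if (stats::var(base$nROH) == 0) stop_param("degenerate baseline: constant nROH")
  fit <- stats::lm(sROH_kb ~ nROH, data = base)
  pred <- stats::predict(fit, newdata = summaries)
  data.frame(sample = summaries$sample,
             residual = summaries$sROH_kb - pred,
             baseline = summaries$sample %in% baseline_samples)
}

# The distance-class upper bounds (kb) as used throughout: note the absence
# of a 40-45 kb class, preserved as printed; include_40_45 adds it back.
ld_bins_default <- function(include_40_45 = FALSE) {
  lower <- c(0, 2, 5, 10, 15, 20, 25, 30, 35, if (include_40_45) 40, 45)
  upper <- c(2, 5, 10, 15, 20, 25, 30, 35, 40, if (include_40_45) 45, Inf)
  labels <- ifelse(is.finite(upper), sprintf("%g-%gkb", lower, upper),
                   sprintf(">%gkb", lower))
  data.frame(lower_kb = lower, upper_kb = upper, label = labels)
}

#' LD decay by distance class
#'
#' Genotype-dosage `r^2` between all SNP pairs within `window_bp`, assigned
#' to distance classes; individuals are downsampled without replacement to
#' `downsample_to`, the whole computation repeated `reps` times, and bin
#' means averaged over replicates.
#'
#' @param g A `genotype_matrix`.
#' @param pop Population label.
#' @param window_bp Maximum pair distance considered.
#' @param bins Distance-class table (default the ten printed classes, which
#'   omit 40-45 kb; see `include_40_45`).
#' @param downsample_to Individuals per replicate.
#' @param reps Downsampling replicates.
#' @param seed Integer seed.
#' @param include_40_45 Add the missing 40-45 kb class.
#' @return `data.frame(label, mean_r2, n_pairs)`.
#' @export
ld_decay <- function(g, pop, window_bp = 1e6, bins = NULL, downsample_to = 5,
                     reps = 10, seed = 1, include_40_45 = FALSE) {
  bins <- bins %||% ld_bins_default(include_40_45)
  rows <- which(g$samples$pop == pop)
  if (length(rows) < downsample_to)
    stop_param("population %s has fewer than %d individuals", pop, downsample_to)
  acc <- matrix(0, nrow = nrow(bins), ncol = reps)
  npair <- numeric(nrow(bins))
  for (rep_i in seq_len(reps)) {
    sub <- with_seed(derive_seed(seed, paste0("ld", rep_i)),
                     sample(rows, downsample_to))
    vals <- vector("list", nrow(bins))
    for (ch in unique(g$sites$chrom)) {
      cols <- which(g$sites$chrom == ch)
      if (length(cols) < 2) next
      d <- g$dosage[sub, cols, drop = FALSE]
      pos <- g$sites$pos[cols]
      sds <- apply(d, 2, stats::sd, na.rm = TRUE)
      poly <- !is.na(sds) & sds > 0
      d <- d[, poly, drop = FALSE]; pos <- pos[poly]
      if (ncol(d) < 2) next
      cm <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
      dist_kb <- abs(outer(pos, pos, "-")) / 1000
      ut <- upper.tri(cm)
      ok <- ut & dist_kb <= window_bp / 1000 & !is.na(cm)
      bin_idx <- findInterval(dist_kb[ok], bins$lower_kb)
      in_bin <- dist_kb[ok] < bins$upper_kb[pmax(bin_idx, 1)] & bin_idx >= 1
      for (b in seq_len(nrow(bins))) {
        sel <- bin_idx == b & in_bin
        if (any(sel)) vals[[b]] <- c(vals[[b]], cm[ok][sel])
      }
    }
    for (b in seq_len(nrow(bins))) {
      acc[b, rep_i] <- if (length(vals[[b]]) > 0) mean(vals[[b]]) else NA
      if (rep_i == 1) npair[b] <- length(vals[[b]])
    }
  }
  data.frame(label = bins$label, mean_r2 = rowMeans(acc, na.rm = TRUE),
             n_pairs = npair)
}

#' Folded site frequency spectrum with downsampling
#'
#' Per replicate, `downsample_to` individuals are sampled without
#' replacement; the folded (minor-allele) frequency spectrum over sites
#' segregating in the subsample is normalized to proportions, and the
#' replicate spectra are averaged. Entry 1 is the singleton proportion.
#'
#' @param g A `genotype_matrix`.
#' @param pop Population label.
#' @param downsample_to Individuals per replicate.
#' @param reps Replicates.
#' @param seed Integer seed.
#' @return Numeric vector of proportions over minor-allele counts
#'   `1..downsample_to`.
#' @export
folded_sfs <- function(g, pop, downsample_to = 5, reps = 10, seed = 1) {
  rows <- which(g$samples$pop == pop)
  if (length(rows) < downsample_to)
    stop_param("population %s has fewer than %d individuals", pop, downsample_to)
  n_alleles <- 2 * downsample_to
  folded_max <- downsample_to
  acc <- matrix(0, folded_max, reps)
  for (rep_i in seq_len(reps)) {
    sub <- with_seed(derive_seed(seed, paste0("sfs", rep_i)),
                     sample(rows, downsample_to))
    d <- g$dosage[sub, , drop = FALSE]
    complete <- colSums(is.na(d)) == 0
    cnt <- colSums(d[, complete, drop = FALSE])
    m <- pmin(cnt, n_alleles - cnt)
    m <- m[m >= 1]
    tab <- tabulate(m, folded_max)
    acc[, rep_i] <- tab / sum(tab)
  }
  stats::setNames(rowMeans(acc), paste0("maf_", seq_len(folded_max)))
}

#' Observed heterozygosity and inbreeding coefficient per individual
#'
#' `Ho_i` is the number of heterozygous sites in individual `i` divided by
#' the total number of SNPs in the dataset. `Fis_i` is the
#' method-of-moments inbreeding coefficient
#' `(O_hom - E_hom) / (N - E_hom)` over `i`'s non-missing sites, with the
#' per-site expected homozygosity `1 - 2 p q n/(n-1)` (small-sample
#' corrected, `n` = sampled allele count; frequencies pooled over all
#' samples).
#'
#' @param g A `genotype_matrix`.
#' @return `data.frame(sample, Ho, Fis)`; `Fis` is `NA` (with a warning)
#'   for an individual with no usable sites.
#' @export
het_stats <- function(g) {
  S <- n_sites(g)
  n_al <- 2 * colSums(!is.na(g$dosage))
  p <- colSums(g$dosage, na.rm = TRUE) / pmax(n_al, 1)
  usable <- n_al > 2 & p > 0 & p < 1
  e_hom_site <- 1 - 2 * p * (1 - p) * n_al / (n_al - 1)
  out <- lapply(seq_len(n_samples(g)), function(i) {
    x <- g$dosage[i, ]
    ho <- sum(x == 1, na.rm = TRUE) / S
    ok <- !is.na(x) & usable
    if (!any(ok)) {
      warning(sprintf("individual %s has no usable sites for Fis", g$samples$id[i]))
      return(data.frame(sample = g$samples$id[i], Ho = ho, Fis = NA_real_))
    }
    o_hom <- sum(x[ok] != 1)
    e_hom <- sum(e_hom_site[ok])
    n_nm <- sum(ok)
    data.frame(sample = g$samples$id[i], Ho = ho,
               Fis = (o_hom - e_hom) / (n_nm - e_hom))
  })
  do.call(rbind, out)
}
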