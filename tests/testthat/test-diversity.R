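test_that("ROH scanning reproduces hand-executed two-pass behaviour", {
  set.seed(1)
  # fully heterozygous chromosome: nothing called
  g_het <- toy_genotypes(matrix(1L, 1, 300), pos = seq_len(300) * 5000L)
  expect_equal(nrow(call_roh(g_het)), 0)

  # 120 homozygous SNPs spaced 5 kb (600 kb) with het-dense flanks:
  # exactly one segment of about 600 kb (window truncation admits a few
  # flanking SNPs at the boundary)
  x <- c(rbinom(200, 2, 0.5), rep(0L, 120), rbinom(200, 2, 0.5))
  g1 <- toy_genotypes(matrix(x, 1), pos = seq_along(x) * 5000L)
  seg <- call_roh(g1)
  expect_equal(nrow(seg), 1)
  expect_gte(seg$n_snps, 120); expect_lte(seg$n_snps, 130)
  expect_gte(seg$length_kb, 595); expect_lte(seg$length_kb, 650)

  # the same run with a 600 kb gap inside: both pieces fail min_snp
  x2 <- c(rbinom(200, 2, 0.5), rep(0L, 120), rbinom(200, 2, 0.5))
  pos2 <- seq_along(x2) * 5000L
  pos2[261:length(pos2)] <- pos2[261:length(pos2)] + 600000L
  g2 <- toy_genotypes(matrix(x2, 1), pos = pos2)
  expect_equal(nrow(call_roh(g2)), 0)

  # unsorted positions are rejected at construction already
  expect_error(toy_genotypes(matrix(0L, 1, 5), pos = c(5L, 4L, 3L, 2L, 1L)),
               "strictly increasing")

  # coordinate-shift invariance of segment structure
  g_shift <- toy_genotypes(matrix(x, 1), pos = seq_along(x) * 5000L + 77000L)
  seg_s <- call_roh(g_shift)
  expect_equal(seg_s$n_snps, seg$n_snps)
  expect_equal(seg_s$length_kb, seg$length_kb)
  expect_equal(seg_s$start - seg$start, 77000)
})

test_that("ROH detection of planted autozygous segments is precise and sensitive", {
  set.seed(2)
  S <- 1200; spacing <- 8000L   # 9.6 Mb chromosome, SNP spacing 8 kb
  pos <- seq_len(S) * spacing
  planted <- list()
  dos <- matrix(0L, 12, S)
  for (i in 1:12) {
    x <- rbinom(S, 2, 0.5)
    start <- sample(100:900, 1)
    len <- sample(140:220, 1)          # 1.1-1.8 Mb
    x[start:(start + len - 1)] <- sample(c(0L, 2L), len, replace = TRUE)
    planted[[i]] <- c(pos[start], pos[start + len - 1])
    dos[i, ] <- x
  }
  g <- toy_genotypes(dos, pos = pos)
  segs <- call_roh(g)
  jacc <- function(a, b) {
    inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
    inter / (max(a[2], b[2]) - min(a[1], b[1]))
  }
  recall_hits <- vapply(1:12, function(i) {
    s <- segs[segs$sample == sprintf("i%02d", i), , drop = FALSE]
    any(vapply(seq_len(nrow(s)), function(k)
      jacc(planted[[i]], c(s$start[k], s$end[k])) >= 0.8, logical(1)))
  }, logical(1))
  precision_hits <- vapply(seq_len(nrow(segs)), function(k) {
    i <- match(segs$sample[k], sprintf("i%02d", 1:12))
    jacc(planted[[i]], c(segs$start[k], segs$end[k])) >= 0.8
  }, logical(1))
  expect_gte(mean(recall_hits), 0.95)
  expect_gte(mean(precision_hits), 0.95)
})

test_that("ROH summaries and the sROH~nROH regression flag inbreeding", {
  segs <- data.frame(sample = c("a", "a", "b", "c", "c", "c"),
                     chrom = "1", start = 1, end = 2,
                     n_snps = 120,
                     length_kb = c(600, 2500, 800, 600, 700, 3000))
  sm <- roh_summary(segs, c("a", "b", "c", "d"))
  expect_equal(sm$nROH, c(2, 1, 3, 0))
  expect_equal(sm$sROH_kb, c(3100, 800, 4300, 0))
  expect_equal(sm$roh_gt_2000kb, c(1, 0, 1, 0))
  expect_equal(sum(sm[sm$sample == "a", c("roh_500_1000kb", "roh_1000_2000kb",
                                          "roh_gt_2000kb")]), 2)

  # baseline exactly on a line: zero residuals, sum-to-zero property
  base <- data.frame(sample = sprintf("b%d", 1:5), nROH = 1:5,
                     sROH_kb = 100 + 50 * (1:5))
  inbred <- data.frame(sample = "x", nROH = 3, sROH_kb = 900)
  res <- roh_regression_residual(rbind(base, inbred), base$sample)
  expect_equal(res$residual[res$baseline], rep(0, 5), tolerance = 1e-9)
  expect_gt(res$residual[res$sample == "x"], 0)
  expect_equal(sum(res$residual[res$baseline]), 0, tolerance = 1e-9)
  bad <- base; bad$nROH <- 3
  expect_error(roh_regression_residual(bad, bad$sample), "degenerate")
})

test_that("LD decay separates duplicated from independent SNP pairs", {
  set.seed(3)
  n <- 12
  base <- rbinom(n, 2, 0.5)
  dos <- cbind(base, base, matrix(rbinom(n * 40, 2, 0.5), n))
  pos <- c(1000L, 2000L, seq(100000, by = 7000, length.out = 40))
  g <- toy_genotypes(dos, pos = pos)
  ld <- ld_decay(g, "p1", downsample_to = 5, reps = 4, seed = 4)
  expect_equal(ld$mean_r2[ld$label == "0-2kb"], 1)
  # independent pairs: mean r2 near the finite-sample floor 1/(n-1) = 0.25
  # at n = 5 individuals, far below the duplicated-pair value, and flat
  mid <- ld$mean_r2[ld$label %in% c("5-10kb", "10-15kb", "15-20kb", "20-25kb")]
  expect_true(all(mid < 0.5 & mid > 0, na.rm = TRUE))
  expect_lt(abs(mean(mid, na.rm = TRUE) - 0.25), 0.15)
  # the printed distance classes omit 40-45 kb unless requested
  expect_false(any(grepl("40-45", ld$label)))
  ld2 <- ld_decay(g, "p1", downsample_to = 5, reps = 2, seed = 4,
                  include_40_45 = TRUE)
  expect_true(any(grepl("40-45", ld2$label)))

  # bottlenecked (cloned) population has higher LD everywhere measurable
  dup <- dos[rep(1:4, 3), ]
  g2 <- toy_genotypes(rbind(dup), pos = pos, pop = rep("bn", 12))
  ld_bn <- ld_decay(g2, "bn", downsample_to = 5, reps = 4, seed = 5)
  cmp <- !is.na(ld_bn$mean_r2) & !is.na(ld$mean_r2) & ld$n_pairs > 0
  expect_gt(mean(ld_bn$mean_r2[cmp]), mean(ld$mean_r2[cmp]))
})

test_that("folded SFS downsampling matches constructed and neutral spectra", {
  # constructed: every site a singleton in the subsample
  dos <- rbind(diag(5) * 1L, matrix(0L, 1, 5))
  storage.mode(dos) <- "integer"
  g <- toy_genotypes(dos, pop = rep("p", 6))
  sfs <- folded_sfs(g, "p", downsample_to = 6, reps = 1, seed = 1)
  expect_equal(unname(sfs), c(1, 0, 0, 0, 0, 0))

  # frequency-draw oracle: genotypes drawn binomially at known frequencies
  # follow the folded binomial sampling spectrum
  set.seed(2)
  S <- 40000
  p <- runif(S, 0.02, 0.98)
  dos2 <- t(vapply(1:12, function(i) rbinom(S, 2, p), numeric(S)))
  g2 <- toy_genotypes(dos2, pop = rep("p", 12))
  got <- folded_sfs(g2, "p", downsample_to = 5, reps = 10, seed = 3)
  # oracle by direct binomial folding of the same frequency distribution
  cnt <- rbinom(S, 10, p)
  m <- pmin(cnt, 10 - cnt); m <- m[m >= 1]
  oracle <- tabulate(m, 5) / sum(tabulate(m, 5))
  expect_equal(unname(got), oracle, tolerance = 0.05)
  expect_equal(sum(got), 1, tolerance = 1e-9)

  # drifted (lower-Ne) population has fewer singletons
  set.seed(4)
  p_drift <- clampfreq <- pmin(pmax(p + rnorm(S, 0, 0.25), 0), 1)
  dos3 <- t(vapply(1:12, function(i) rbinom(S, 2, p_drift), numeric(S)))
  g3 <- toy_genotypes(dos3, pop = rep("p", 12))
  got3 <- folded_sfs(g3, "p", downsample_to = 5, reps = 10, seed = 5)
  expect_lt(got3[1], got[1])
  expect_error(folded_sfs(g3, "p", downsample_to = 50), "fewer")
})

test_that("Ho and Fis have the right anchors and anti-correlate under autozygosity", {
  # hand count: 3 het of 10 SNPs
  dos <- matrix(c(rep(1L, 3), rep(0L, 7)), 1)
  dos <- rbind(dos, matrix(rbinom(40, 2, 0.5), 4))
  g <- toy_genotypes(dos, pop = rep("p", 5))
  hs <- het_stats(g)
  expect_equal(hs$Ho[1], 0.3)

  # HWE population: Fis near zero
  set.seed(5)
  S <- 60000
  p <- runif(S, 0.1, 0.9)
  dosh <- t(vapply(1:20, function(i) rbinom(S, 2, p), numeric(S)))
  gh <- toy_genotypes(dosh, pop = rep("p", 20))
  hsh <- het_stats(gh)
  expect_lt(max(abs(hsh$Fis)), 0.05)

  # fully homozygous individual at segregating sites: Fis = 1
  dosf <- dosh
  dosf[1, ] <- ifelse(rbinom(S, 1, p) == 1, 2L, 0L)
  hsf <- het_stats(toy_genotypes(dosf, pop = rep("p", 20)))
  expect_equal(hsf$Fis[1], 1, tolerance = 1e-9)

  # planted autozygosity: Ho and Fis strongly anti-correlated
  set.seed(6)
  lam <- seq(0, 0.9, length.out = 10)
  dosa <- t(vapply(lam, function(l) {
    auto <- rbinom(S, 1, l) == 1
    x <- rbinom(S, 2, p)
    x[auto] <- ifelse(rbinom(sum(auto), 1, p[auto]) == 1, 2L, 0L)
    as.numeric(x)
  }, numeric(S)))
  hsa <- het_stats(toy_genotypes(dosa, pop = rep("p", 10)))
  expect_lte(stats::cor(hsa$Ho, hsa$Fis, method = "spearman"), -0.9)
})
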