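test_that("source frequencies follow the Balding-Nichols structure", {
  # zero-differentiation limit: frequencies collapse onto the ancestral ones
  sf <- sample_source_frequencies(5000, c(1e-6, 1e-6), seed = 1)
  close <- abs(sf$freq[1, ] - sf$anc_freq) < 0.01
  expect_gt(mean(close), 0.99)
  expect_true(all(sf$freq >= 0 & sf$freq <= 1))
  expect_true(all(sf$anc_freq >= 0.05 & sf$anc_freq <= 0.95))

  # determinism under a fixed seed
  sf2 <- sample_source_frequencies(5000, c(1e-6, 1e-6), seed = 1)
  expect_identical(sf$freq, sf2$freq)

  expect_error(sample_source_frequencies(100, c(0, 0.1)), "fst")
  expect_error(sample_source_frequencies(100, c(NA, 0.1)), "fst")
})

test_that("population-level Hudson Fst of a simulated pair matches the Monte-Carlo oracle", {
  # oracle: average per-site numerator/denominator computed directly from
  # the Beta draws at the population (not sample) level
  F <- 0.027
  sf <- sample_source_frequencies(150000, c(F, F), seed = 7)
  p1 <- sf$freq[1, ]; p2 <- sf$freq[2, ]
  oracle <- sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
  # sample-level estimator on binomially drawn genotype counts must agree
  set.seed(8)
  pa <- rbinom(150000, 18, p1) / 18
  pb <- rbinom(150000, 16, p2) / 16
  est <- maroongen:::hudson_fst_counts(pa, rep(18, 150000), pb, rep(16, 150000))$fst
  expect_equal(est, oracle, tolerance = 0.05)
  # and both sit near the Balding-Nichols F parameter for small F
  expect_equal(oracle, F, tolerance = 0.08)
})

test_that("calibrate_fst is self-consistent on re-simulation", {
  expect_lt(as.numeric(calibrate_fst(0)), 1e-4)
  F <- calibrate_fst(0.027, n_sites = 1e5, sample_sizes = c(9, 8), seed = 3)
  # re-simulate with a fresh seed at the calibrated F
  sf <- sample_source_frequencies(150000, c(F, F), seed = 101)
  set.seed(102)
  pa <- rbinom(150000, 18, sf$freq[1, ]) / 18
  pb <- rbinom(150000, 16, sf$freq[2, ]) / 16
  got <- maroongen:::hudson_fst_counts(pa, rep(18, 150000), pb, rep(16, 150000))$fst
  expect_gte(got, 0.0257)
  expect_lte(got, 0.0284)
})

test_that("admixed genotypes track their ancestry proportions", {
  sf <- sample_source_frequencies(4000, c(0.3, 0.3, 0.3), seed = 2)
  # pure-source cohort reproduces source-1 frequencies
  g <- simulate_admixed_genotypes(sf, admixture_spec("P", c(1, 0, 0), 50), seed = 3)
  obs <- colMeans(g$dosage) / 2
  # chi-square GOF over sites (binomial allele counts at known frequency)
  z <- (100 * obs - 100 * sf$freq[1, ]) /
    sqrt(pmax(100 * sf$freq[1, ] * (1 - sf$freq[1, ]), 1e-9))
  pval <- stats::pchisq(sum(z^2), df = length(z), lower.tail = FALSE)
  expect_gt(pval, 0.001)

  # regression of realized ancestry dosage on spec proportions: slope 1
  specs <- lapply(1:6, function(i) {
    a <- c(0.1 + 0.1 * i, 0.8 - 0.1 * i, 0.1)
    admixture_spec(paste0("c", i), a / sum(a), 4)
  })
  g2 <- simulate_admixed_genotypes(sample_source_frequencies(150000, rep(0.1, 3), seed = 4),
                                   specs, seed = 5)
  truth <- attr(g2, "truth")
  expected <- do.call(rbind, lapply(specs, function(s)
    matrix(s$proportions, s$n_individuals, 3, byrow = TRUE)))
  fit <- stats::lm(as.vector(truth) ~ as.vector(expected))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)

  expect_error(simulate_admixed_genotypes(sf, admixture_spec("x", c(1, 0), 2)),
               "proportions")
})

test_that("haplotype mosaics carry correct ancestry tracks", {
  set.seed(1)
  src <- list(a = matrix(rbinom(40, 1, 0.5), 4), b = matrix(rbinom(40, 1, 0.5), 4))
  # switch_rate -> 0: single segment from one donor
  m <- simulate_haplotype_mosaic(src, c(0.5, 0.5), 1e-9, 3, seed = 2)
  expect_true(all(vapply(m$tracks, nrow, integer(1)) == 1))
  # proportions (1, 0): all segments labelled source 1
  m2 <- simulate_haplotype_mosaic(src, c(1, 0), 0.3, 5, seed = 3)
  expect_true(all(unlist(lapply(m2$tracks, function(t) t$source)) == 1))
  # Poisson oracle on switch counts at 10k sites, rate 1e-3
  set.seed(4)
  big <- list(a = matrix(rbinom(2e4, 1, 0.5), 2), b = matrix(rbinom(2e4, 1, 0.5), 2))
  m3 <- simulate_haplotype_mosaic(big, c(0.5, 0.5), 1e-3, 40, seed = 5)
  lambda <- (1e4 - 1) * 1e-3
  se <- sqrt(lambda / 40)
  expect_lt(abs(mean(m3$n_switches) - lambda), 3 * se)
  expect_error(simulate_haplotype_mosaic(list(a = matrix(0, 1, 10)), 1, 0.1, 1),
               "2 haplotypes")
})

test_that("duo simulation produces the expected KING kinship tiers", {
  sf <- sample_source_frequencies(150000, c(0.027, 0.027), seed = 11)
  clone <- simulate_duo(sf, seed = 12, clone = TRUE)
  expect_gte(king_kinship(clone, "parent", "offspring"), 0.45)
  duo <- simulate_duo(sf, n_unrelated = 1, seed = 13)
  phi_po <- king_kinship(duo, "parent", "offspring")
  expect_gte(phi_po, 0.20); expect_lte(phi_po, 0.30)
  phi_un <- king_kinship(duo, "parent", "unrel_01")
  expect_gte(phi_un, -0.05); expect_lte(phi_un, 0.05)
})

test_that("Y-STR star simulation matches its Poisson mutation model", {
  founder <- rep(14L, 10)
  g0 <- simulate_ystr("star", founder, 0, mu = 0.0025, n_lineages = 20, seed = 1)
  expect_true(all(g0$haplotypes == 14))
  # mean per-lineage mutation count ~ L * mu * g
  ys <- simulate_ystr("star", founder, 16.67, mu = 0.0025, n_lineages = 24000, seed = 2)
  lambda <- 10 * 0.0025 * 16.67
  expect_equal(mean(attr(ys, "n_mutations")), lambda, tolerance = 0.03)
  expect_true(all(ys$haplotypes >= 1))
  expect_error(simulate_ystr("star", founder[1:3], 5, n_lineages = 5,
                             loci = paste0("L", 1:4)), "founder")
})

test_that("Wright-Fisher lineage frequency is a martingale when b = 1", {
  m <- dominance_model(0.05, 1, tau = 1, p0 = 0.2, q0 = 1)
  finals <- vapply(1:300, function(r) {
    ys <- simulate_ystr("wright_fisher", rep(14L, 5), 6, mu = 0.001,
                        n_lineages = 200, dominance = m, seed = 1000 + r)
    utils::tail(attr(ys, "lineage_freq"), 1)
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.2), 3 * se)
})

test_that("sequence simulation yields countable diversity", {
  s0 <- simulate_sequences(strrep("ACGT", 75), 5, 0, seed = 1)
  expect_true(all(s0 == s0[1]))
  expect_identical(attr(s0, "segregating_sites"), 0L)
  expect_error(simulate_sequences("ACGX", 2, 0.1), "invalid characters")
  expect_error(simulate_sequences("", 2, 0.1), "empty")
})

test_that("genotypes round-trip through the VCF writer and reader", {
  sf <- sample_source_frequencies(300, c(0.1, 0.1), seed = 21)
  g <- simulate_admixed_genotypes(sf, list(admixture_spec("A", c(1, 0), 3),
                                           admixture_spec("B", c(0, 1), 3)), seed = 22)
  g$dosage[1, 5] <- NA  # missing genotype survives the round trip
  path <- tempfile(fileext = ".vcf.gz")
  write_vcf(g, path)
  pops <- data.frame(sample_id = g$samples$id, population = g$samples$pop)
  g2 <- read_vcf(path, pops)
  expect_identical(unname(g2$dosage), unname(g$dosage))
  expect_identical(g2$sites$pos, g$sites$pos)
  expect_identical(g2$samples$pop, g$samples$pop)

  # phased round trip
  set.seed(23)
  panel <- hap_panel(matrix(rbinom(40, 1, 0.5), 4),
                     data.frame(chrom = "1", pos = 1:10 * 100, ref = "A", alt = "C"),
                     rep(c("x", "y"), each = 2), rep(c("p", "q"), each = 2))
  p2 <- tempfile(fileext = ".vcf.gz")
  write_vcf(panel, p2)
  back <- read_phased_vcf(p2, data.frame(sample_id = c("x", "y"),
                                         population = c("p", "q")))
  expect_identical(unname(back$haps), unname(panel$haps))
})
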