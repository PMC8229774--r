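test_that("TVD is a metric on copy profiles", {
  expect_equal(tvd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(tvd(c(1, 0), c(0, 1)), 1)
  expect_equal(tvd(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3)), 0.4)
  expect_error(tvd(c(1, 0), c(1, 0, 0)), "donor bases")
  # metric axioms on random profiles
  set.seed(1)
  for (i in 1:2000) {
    x <- maroongen:::rdirichlet(1, rep(0.5, 5))[1, ]
    y <- maroongen:::rdirichlet(1, rep(0.5, 5))[1, ]
    z <- maroongen:::rdirichlet(1, rep(0.5, 5))[1, ]
    dxy <- tvd(x, y); dyz <- tvd(y, z); dxz <- tvd(x, z)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
    expect_equal(dxy, tvd(y, x))
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
  expect_equal(tvd(c(0.3, 0.7), c(0.3, 0.7)), 0)
})

test_that("NJ reconstructs additive distance matrices exactly", {
  # 3-taxon closed form
  d3 <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  pend <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(pend[c("A", "B", "C")]), c(0.1, 0.2, 0.3), tolerance = 1e-12)

  # random additive matrices: patristic distances reproduce the input
  for (seed in 1:5) {
    ref <- random_additive_matrix(7, seed = seed)
    tr <- nj_tree(ref$d)
    got <- cophenetic(tr)[rownames(ref$d), colnames(ref$d)]
    expect_lt(max(abs(got - ref$d)), 1e-10)
  }

  # taxon permutation gives an isomorphic tree
  ref <- random_additive_matrix(6, seed = 9)
  perm <- c(4, 1, 6, 2, 5, 3)
  tr_p <- nj_tree(ref$d[perm, perm])
  got <- cophenetic(tr_p)[rownames(ref$d), colnames(ref$d)]
  expect_lt(max(abs(got - ref$d)), 1e-10)

  d_bad <- ref$d; d_bad[1, 2] <- NA
  expect_error(nj_tree(d_bad), "NA")
})

test_that("NJ on linear-mixture TVD matrices reproduces the line geometry", {
  # profiles on a segment between two endpoints: TVD is proportional to the
  # mixture-coefficient difference and the NJ tree embeds the line exactly
  alphas <- c(P1 = 0, P2 = 0.25, P3 = 0.58, P4 = 0.8, P5 = 1)
  p_g <- copy_profile(c(5, 3, 1, 0.5, 0.5))
  p_a <- copy_profile(c(0.5, 0.5, 1, 3, 5))
  prof <- do.call(rbind, lapply(alphas, function(a) a * p_g + (1 - a) * p_a))
  rownames(prof) <- names(alphas)
  tm <- tvd_matrix(prof)
  scale <- tvd(p_g, p_a)
  expect_equal(tm["P1", "P5"], scale, tolerance = 1e-12)
  expect_equal(tm["P2", "P4"], 0.55 * scale, tolerance = 1e-12)
  tr <- nj_tree(tm)
  got <- cophenetic(tr)[rownames(tm), colnames(tm)]
  expect_lt(max(abs(got - tm)), 1e-9)
})

test_that("bootstrap support is 1 for deterministic profiles and reproducible", {
  coh <- linear_profile_cohort(c(A = 0, B = 0.4, C = 0.7, D = 1), n_per = 6,
                               conc = 1e9, seed = 2)  # essentially noise-free
  tr <- bootstrap_support(coh$profiles, coh$labels, n_reps = 60, seed = 3)
  expect_true(all(tr$node.label[!is.na(tr$node.label)] >= 0.999))
  tr2 <- bootstrap_support(coh$profiles, coh$labels, n_reps = 60, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  # interleaved populations with identical profile distributions: at least
  # one split has weak support
  set.seed(4)
  noisy <- maroongen:::rdirichlet(36, rep(2, 5))
  labs <- rep(c("U", "V", "W", "X", "Y", "Z"), times = 6)
  tr3 <- bootstrap_support(noisy, labs, n_reps = 200, seed = 5)
  expect_lte(min(tr3$node.label, na.rm = TRUE), 0.8)
  expect_error(bootstrap_support(noisy, labs, n_reps = 0), "n_reps")
})

test_that("Bernstein's equation interpolates ancestry components", {
  expect_equal(as.numeric(bernstein(0.9, 0.9, 0.1)), 1)
  expect_equal(as.numeric(bernstein(0.1, 0.9, 0.1)), 0)
  expect_equal(as.numeric(bernstein(0.42, 0.9, 0.1)), 0.4)
  # two marker components averaged
  expect_equal(as.numeric(bernstein(c(0.42, 0.5), c(0.9, 0.9), c(0.1, 0.1))),
               mean(c(0.4, 0.5)))
  b <- bernstein(0.95, 0.9, 0.1)
  expect_true(attr(b, "clamped"))
  expect_equal(as.numeric(b), 1)
  expect_error(bernstein(0.5, 0.3, 0.3), "equal")
})

test_that("PCA centroid projection recovers planted fractions", {
  # exact geometry: centroids at (0,0) and (1,0), targets on and off axis
  coords <- rbind(a1 = c(0, 0.1), a2 = c(0, -0.1),
                  b1 = c(1, 0.1), b2 = c(1, -0.1),
                  t_mid = c(0.5, 0.4), t_a = c(0, 0.9), t_out = c(1.3, 0))
  est <- pca_projection_ancestry(coords, c("a1", "a2"), c("b1", "b2"),
                                 c("t_mid", "t_a", "t_out"))
  expect_equal(est$prop_a[est$id == "t_mid"], 0.5)
  expect_equal(est$prop_a[est$id == "t_a"], 1)
  expect_true(est$clamped[est$id == "t_out"])
  expect_error(pca_projection_ancestry(coords, c("a1", "a2"), c("a1", "a2"),
                                       "t_mid"), "coincident")

  # simulated cohort at 76% Gulf-of-Guinea ancestry (of the African portion)
  sf <- sample_source_frequencies(60000, c(0.16, 0.03, 0.03), seed = 6)
  specs <- list(admixture_spec("EUR", c(1, 0, 0), 10),
                admixture_spec("GOG", c(0, 1, 0), 10),
                admixture_spec("ANG", c(0, 0, 1), 10),
                admixture_spec("TGT", c(0.03, 0.97 * 0.76, 0.97 * 0.24), 7))
  g <- simulate_admixed_genotypes(sf, specs, seed = 7)
  pc <- pca(g, n_components = 2)
  pops <- g$samples$pop; ids <- g$samples$id
  est2 <- pca_projection_ancestry(pc, ids[pops == "GOG"], ids[pops == "ANG"],
                                  ids[pops == "TGT"])
  expect_equal(mean(est2$prop_a), 0.76, tolerance = 0.05 / 0.76)
})

test_that("tree-geometry ancestry recovers linear-mixture fractions", {
  alphas <- c(TGT = 0.58, FOR = 0.64, PRI = 0.69, YRI = 1, GWD = 0.97,
              GAN = 0, NYK = 0.02, HIM = 0.05)
  coh <- linear_profile_cohort(alphas, n_per = 8, conc = 3000, seed = 8)
  avg <- avg_profiles_by(coh$profiles, coh$labels)
  tr <- nj_tree(tvd_matrix(avg))
  est <- nj_geometry_ancestry(tr, "TGT", "YRI", c("GAN", "NYK"))
  expect_equal(est$proportion[est$source == "gulf_of_guinea"], 0.58,
               tolerance = 0.04 / 0.58)
  # degenerate anchors of the estimator
  expect_equal(
    nj_geometry_ancestry(tr, "YRI", "YRI", c("GAN", "NYK"))$proportion[1], 1)
  # leaf mode and literal reading are exposed
  est_leaf <- nj_geometry_ancestry(tr, "TGT", "YRI", c("GAN", "NYK"),
                                   node = "leaf")
  expect_equal(est_leaf$proportion[1], 0.58, tolerance = 0.08 / 0.58)
  est_lit <- nj_geometry_ancestry(tr, "TGT", "YRI", c("GAN", "NYK"),
                                  reading = "literal")
  expect_equal(est_lit$proportion[1] + est$proportion[1], 1, tolerance = 1e-9)
  expect_error(nj_geometry_ancestry(tr, "nope", "YRI", c("GAN", "NYK")),
               "leaves")
})

test_that("all three estimators are monotone in the true ancestry fraction", {
  # noise-free linear profiles: estimates within +-5 points and monotone
  p_g <- copy_profile(c(5, 3, 1, 0.5, 0.5))
  p_a <- copy_profile(c(0.5, 0.5, 1, 3, 5))
  fractions <- c(0.2, 0.4, 0.6, 0.8)
  ests <- vapply(fractions, function(a) {
    alphas <- c(TGT = a, YRI = 1, GWD = 0.95, GAN = 0, NYK = 0.03, HIM = 0.06)
    prof <- do.call(rbind, lapply(alphas, function(x) x * p_g + (1 - x) * p_a))
    rownames(prof) <- names(alphas)
    tr <- nj_tree(tvd_matrix(prof))
    nj_geometry_ancestry(tr, "TGT", "YRI", c("GAN", "NYK"))$proportion[1]
  }, numeric(1))
  expect_true(all(abs(ests - fractions) <= 0.05))
  expect_true(all(diff(ests) > 0))

  bern <- vapply(fractions, function(a)
    as.numeric(bernstein(a * 0.9 + (1 - a) * 0.1, 0.9, 0.1)), numeric(1))
  expect_equal(bern, fractions, tolerance = 1e-12)

  coords <- rbind(G = c(0, 0), A = c(1, 0),
                  t1 = c(0.8, 0), t2 = c(0.6, 0), t3 = c(0.4, 0), t4 = c(0.2, 0))
  proj <- pca_projection_ancestry(coords, "G", "A", c("t1", "t2", "t3", "t4"))
  expect_equal(proj$prop_a, fractions, tolerance = 1e-12)
})
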