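# Fixture builders shared across test files. Everything is generated in
# code so tests are self-contained and deterministic.

toy_genotypes <- function(dosage, chrom = NULL, pos = NULL, ref = NULL,
                          alt = NULL, pop = NULL, depth = NULL, qual = NULL) {
  dosage <- as.matrix(dosage)
  S <- ncol(dosage); N <- nrow(dosage)
  genotype_matrix(
    dosage,
    data.frame(chrom = chrom %||% rep("1", S),
               pos = pos %||% (seq_len(S) * 1000L),
               ref = ref %||% rep("A", S),
               alt = alt %||% rep("G", S)),
    data.frame(id = sprintf("i%02d", seq_len(N)),
               pop = pop %||% rep("p1", N)),
    depth = depth, qual = qual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force exact HWE p-value by enumerating heterozygote configurations
hwe_bruteforce <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  w <- vapply(hets, function(h) {
    hom1 <- (nA - h) / 2; hom2 <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(hom1) - lfactorial(h) - lfactorial(hom2) +
          h * log(2))
  }, numeric(1))
  p <- w / sum(w)
  sum(p[p <= p[match(nAa, hets)] + 1e-12])
}

# individual copy profiles that are linear mixtures of two endpoint
# profiles with Dirichlet noise; returns list(profiles, labels)
linear_profile_cohort <- function(alphas, n_per = 8, conc = 3000, seed = 1) {
  p_gog <- copy_profile(c(5, 3, 1, 0.5, 0.5))
  p_ang <- copy_profile(c(0.5, 0.5, 1, 3, 5))
  maroongen:::with_seed(seed, {
    prof <- do.call(rbind, lapply(names(alphas), function(p) {
      base <- alphas[[p]] * p_gog + (1 - alphas[[p]]) * p_ang
      maroongen:::rdirichlet(n_per, conc * base)
    }))
    list(profiles = prof, labels = rep(names(alphas), each = n_per),
         p_gog = p_gog, p_ang = p_ang)
  })
}

avg_profiles_by <- function(profiles, labels) {
  out <- do.call(rbind, lapply(sort(unique(labels)), function(p)
    colMeans(profiles[labels == p, , drop = FALSE])))
  rownames(out) <- sort(unique(labels))
  out
}

# a random additive distance matrix from a known random tree
random_additive_matrix <- function(n_taxa, seed = 1) {
  maroongen:::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
    list(tree = tr, d = cophenetic(tr))
  })
}
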