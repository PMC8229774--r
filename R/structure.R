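# Genotype-based population structure: LD pruning, Patterson-normalized PCA,
# unsupervised admixture EM, and Hudson Fst.

#' Sliding-window LD pruning
#'
#' Within each `window`-SNP window (slid by `step` SNPs), any pair of kept
#' SNPs with genotype-dosage correlation `r^2 > r2_max` triggers removal of
#' the later SNP. Deterministic; returns a strictly increasing index list.
#'
#' @param g A `genotype_matrix`.
#' @param window Window size in SNPs.
#' @param step Window increment in SNPs.
#' @param r2_max Squared-correlation threshold.
#' @return Integer vector of retained site indices.
#' @export
ld_prune <- function(g, window = 200, step = 5, r2_max = 0.2) {
  if (!(window > step && step >= 1)) stop_param("need window > step >= 1")
  S <- n_sites(g)
  keep <- rep(TRUE, S)
  starts <- seq(1, max(1, S - 1), by = step)
  for (st in starts) {
    en <- min(st + window - 1, S)
    idx <- which(keep[st:en]) + st - 1
    if (length(idx) < 2) next
    cm <- suppressWarnings(stats::cor(g$dosage[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)[-seq_len(a)]) {
        if (!keep[idx[b]]) next
        if (cm[a, b]^2 > r2_max) keep[idx[b]] <- FALSE
      }
    }
    if (en == S) break
  }
  which(keep)
}

#' Principal component analysis of genotypes or coancestry profiles
#'
#' Genotype mode: monomorphic sites are dropped, dosages are centered and
#' scaled by `sqrt(p(1-p))` (Patterson normalization), missing entries are
#' mean-imputed (zero after normalization), and the eigendecomposition of
#' the individual covariance gives the coordinates. Coancestry mode: PCA of
#' the row-centered chunk-count matrix.
#'
#' @param x A `genotype_matrix` or `coancestry` object.
#' @param n_components Number of components to return.
#' @return A `pca_result`: `coordinates` (individuals x components,
#'   1-based component index), `explained` (variance fractions).
#' @export
pca <- function(x, n_components = 2) {
  if (inherits(x, "coancestry")) {
    m <- x$chunk_counts
    M <- sweep(m, 1, rowMeans(m))
    ids <- rownames(m)
  } else {
    p <- colMeans(x$dosage, na.rm = TRUE) / 2
    poly <- !is.na(p) & p > 0 & p < 1
    d <- x$dosage[, poly, drop = FALSE]
    p <- p[poly]
    M <- sweep(d, 2, 2 * p) / rep(sqrt(p * (1 - p)), each = nrow(d))
    M[is.na(M)] <- 0
    ids <- x$samples$id
  }
  if (nrow(M) < 2) stop_param("need at least 2 individuals")
  K <- tcrossprod(M) / ncol(M)
  eig <- eigen(K, symmetric = TRUE)
  pos <- sum(eig$values > 1e-12)
  k <- min(n_components, pos)
  if (k < n_components)
    warning(sprintf("rank %d < %d requested components; truncating", pos, n_components))
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  rownames(coords) <- ids
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 explained = eig$values[seq_len(k)] / sum(pmax(eig$values, 0))),
            class = "pca_result")
}

#' Unsupervised admixture estimation by EM
#'
#' Fits the binomial admixture likelihood
#' `prod_i prod_s Bin(g_is | 2, sum_k Q_ik F_ks)` by plain EM (the same
#' likelihood the block-relaxation solvers optimize), taking the best of
#' `n_restarts` random initializations. Cluster labels are made
#' deterministic by sorting clusters in lexicographic order of their
#' frequency vectors. The log-likelihood is asserted non-decreasing.
#'
#' @param g A `genotype_matrix` (LD-pruned input recommended).
#' @param K Number of clusters (K = 1 allowed; closed form).
#' @param n_restarts Random restarts.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param seed Integer seed.
#' @return An `admixture_result`: `Q` (individuals x K), `F` (K x sites),
#'   `loglik`.
#' @export
admixture_em <- function(g, K, n_restarts = 20, max_iter = 300, tol = 1e-6,
                         seed = 1) {
  d <- g$dosage
  N <- nrow(d); S <- ncol(d)
  obs <- !is.na(d)
  d0 <- d; d0[!obs] <- 0
  if (K == 1) {
    Fm <- matrix(colMeans(d, na.rm = TRUE) / 2, nrow = 1)
    Q <- matrix(1, N, 1)
    ll <- admixture_loglik(d0, obs, Q, Fm)
    return(structure(list(Q = Q, F = Fm, loglik = ll), class = "admixture_result"))
  }
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    res <- with_seed(derive_seed(seed, paste0("restart", rs)), {
      Q <- rdirichlet(N, rep(1, K))
      Fm <- matrix(stats::runif(K * S, 0.05, 0.95), K, S)
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        P <- Q %*% Fm
        P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
        A <- d0 / P          # expected derived-copy weight
        B <- (2 - d0) / (1 - P)
        A[!obs] <- 0; B[!obs] <- 0
        Qn <- matrix(0, N, K); Fn_num <- matrix(0, K, S); Fn_den <- matrix(0, K, S)
        for (k in seq_len(K)) {
          a_k <- A * (Q[, k] %o% Fm[k, ])        # N x S expected derived from k
          b_k <- B * (Q[, k] %o% (1 - Fm[k, ]))  # expected ancestral from k
          Qn[, k] <- rowSums(a_k + b_k)
          Fn_num[k, ] <- colSums(a_k)
          Fn_den[k, ] <- colSums(a_k + b_k)
        }
        Q <- Qn / rowSums(Qn)
        Fm <- Fn_num / pmax(Fn_den, 1e-12)
        Fm <- pmin(pmax(Fm, 1e-6), 1 - 1e-6)
        ll <- admixture_loglik(d0, obs, Q, Fm)
        if (ll < ll_old - 1e-6) stop("internal error: admixture EM likelihood decreased")
        if (ll - ll_old < tol) break
        ll_old <- ll
      }
      list(Q = Q, F = Fm, loglik = ll)
    })
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  ord <- do.call(order, as.data.frame(best$F)[, seq_len(min(200, S)), drop = FALSE])
  best$F <- best$F[ord, , drop = FALSE]
  best$Q <- best$Q[, ord, drop = FALSE]
  rownames(best$Q) <- g$samples$id
  structure(best, class = "admixture_result")
}

admixture_loglik <- function(d0, obs, Q, Fm) {
  P <- Q %*% Fm
  P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
  ll <- d0 * log(P) + (2 - d0) * log(1 - P)
  sum(ll[obs])
}

#' Hudson Fst between two populations
#'
#' Ratio-of-averages estimator: per-site numerator
#' `(pa-pb)^2 - pa(1-pa)/(na-1) - pb(1-pb)/(nb-1)` and denominator
#' `pa(1-pb) + pb(1-pa)` (allele counts `na`, `nb`), with Fst the ratio of
#' the sums. A Weir-Cockerham variant is available behind `method`.
#'
#' @param g A `genotype_matrix`.
#' @param pop_a,pop_b Population labels.
#' @param method `"hudson"` (default) or `"wc"`.
#' @return Fst (scalar) with attribute `components`
#'   (`data.frame(num, den)` per usable site).
#' @export
hudson_fst <- function(g, pop_a, pop_b, method = c("hudson", "wc")) {
  method <- match.arg(method)
  for (p in c(pop_a, pop_b))
    if (!p %in% g$samples$pop) stop_param("population '%s' absent", p)
  da <- g$dosage[g$samples$pop == pop_a, , drop = FALSE]
  db <- g$dosage[g$samples$pop == pop_b, , drop = FALSE]
  na_ <- 2 * colSums(!is.na(da)); nb_ <- 2 * colSums(!is.na(db))
  pa <- colSums(da, na.rm = TRUE) / pmax(na_, 1)
  pb <- colSums(db, na.rm = TRUE) / pmax(nb_, 1)
  if (method == "hudson") {
    h <- hudson_fst_counts(pa, na_, pb, nb_)
    return(structure(h$fst, components = data.frame(num = h$num, den = h$den)))
  }
  # Weir-Cockerham, alleles as units (haploid analysis-of-variance form)
  ok <- na_ > 1 & nb_ > 1
  pa <- pa[ok]; pb <- pb[ok]; n1 <- na_[ok]; n2 <- nb_[ok]
  pbar <- (n1 * pa + n2 * pb) / (n1 + n2)
  msp <- n1 * (pa - pbar)^2 + n2 * (pb - pbar)^2
  msg <- (n1 * pa * (1 - pa) + n2 * pb * (1 - pb)) / (n1 + n2 - 2)
  nc <- n1 + n2 - (n1^2 + n2^2) / (n1 + n2)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  keep <- den > 0
  structure(sum(num[keep]) / sum(den[keep]),
            components = data.frame(num = num, den = den))
}

#' Pairwise Fst matrix over all populations
#' @param g A `genotype_matrix`.
#' @param method Passed to [hudson_fst()].
#' @return Symmetric matrix of pairwise Fst.
#' @export
fst_matrix <- function(g, method = "hudson") {
  pops <- sort(unique(g$samples$pop))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)[-seq_len(i)]) {
    m[i, j] <- m[j, i] <- as.numeric(hudson_fst(g, pops[i], pops[j], method = method))
  }
  m
}

#' UPGMA tree of a distance matrix
#'
#' Average-linkage clustering of (for example) a pairwise Fst matrix; the
#' returned tree is ultrametric with cophenetic distances equal to merge
#' heights.
#'
#' @param d Symmetric distance matrix.
#' @return An [ape::as.phylo()] tree.
#' @export
upgma_tree <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}
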