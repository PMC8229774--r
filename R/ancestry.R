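# Ancestry inference from copy profiles: total variation distance,
# Neighbor-Joining trees with bootstrap support, and three admixture
# proportion estimators (Bernstein, PCA centroid projection, tree geometry).

#' Normalize a copy profile
#' @param x Nonnegative vector over donor groups.
#' @return `x / sum(x)`.
#' @export
copy_profile <- function(x) {
  if (any(x < 0)) stop_param("profile entries must be nonnegative")
  if (sum(x) <= 0) stop_param("profile sums to zero")
  x / sum(x)
}

#' Total variation distance between two copy profiles
#'
#' `TVD(x, y) = 0.5 * sum_k |x_k - y_k|`, a metric on the probability
#' simplex with values in \[0, 1\].
#'
#' @param x,y Normalized profiles on the same donor-group basis (names are
#'   checked when present).
#' @return TVD (scalar).
#' @export
tvd <- function(x, y) {
  if (length(x) != length(y)) stop_param("profiles have different donor bases")
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y)))
    stop_param("profile donor-group names differ")
  0.5 * sum(abs(x - y))
}

#' Pairwise TVD matrix from population profiles
#' @param profiles Matrix, populations in rows, donor groups in columns.
#' @return Symmetric distance matrix.
#' @export
tvd_matrix <- function(profiles) {
  n <- nrow(profiles)
  m <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n)) for (j in seq_len(n)[-seq_len(i)])
    m[i, j] <- m[j, i] <- tvd(profiles[i, ], profiles[j, ])
  m
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei NJ (via [ape::nj()]); negative branch lengths are truncated
#' to zero with the deficit transferred to the sibling branch, so total
#' path lengths through the parent node are preserved. Additive matrices
#' are reconstructed exactly.
#'
#' @param d Symmetric distance matrix (zero diagonal, >= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d))) stop_param("distance matrix contains NA")
  if (nrow(d) < 3) stop_param("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    if (length(sib) > 0) {
      tr$edge.length[sib[1]] <- max(0, tr$edge.length[sib[1]] + deficit)
    }
  }
  tr
}

#' NJ tree with bootstrap split support
#'
#' Builds the main tree from population-averaged individual copy profiles,
#' then resamples individuals with replacement within each population
#' `n_reps` times, recomputing averaged profiles, the TVD matrix and the NJ
#' tree; the support of each internal split is the fraction of replicate
#' trees containing it (stored in `node.label`).
#'
#' @param profiles Matrix of individual copy profiles (rows) over donor
#'   groups (columns).
#' @param labels Population label per individual.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A `phylo` tree with `node.label` support values in \[0, 1\].
#' @export
bootstrap_support <- function(profiles, labels, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop_param("n_reps must be >= 1")
  labels <- as.character(labels)
  avg_profiles <- function(prof) {
    out <- do.call(rbind, lapply(sort(unique(labels)), function(p) {
      colMeans(prof[labels == p, , drop = FALSE])
    }))
    rownames(out) <- sort(unique(labels))
    out
  }
  main <- nj_tree(tvd_matrix(avg_profiles(profiles)))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- unlist(lapply(sort(unique(labels)), function(p) {
        rows <- which(labels == p)
        sample(rows, length(rows), replace = TRUE)
      }))
      prof <- profiles[idx, , drop = FALSE]
      lab_r <- labels[idx]
      pm <- do.call(rbind, lapply(sort(unique(lab_r)), function(p)
        colMeans(prof[lab_r == p, , drop = FALSE])))
      rownames(pm) <- sort(unique(lab_r))
      nj_tree(tvd_matrix(pm))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- counts / n_reps
  main
}

#' Bernstein's admixture-proportion equation
#'
#' Linear interpolation of a marker (allele frequency or ancestry-component
#' proportion) between two source populations:
#' `m_a = (q_hybrid - q_source_b) / (q_source_a - q_source_b)`, clamped to
#' \[0, 1\]. When vectors of marker components are supplied, per-component
#' estimates are computed and averaged with equal weights.
#'
#' @param q_hybrid Marker value(s) in the admixed population.
#' @param q_source_a,q_source_b Marker value(s) in the two sources.
#' @return Estimated proportion of source A, with attribute `clamped`.
#' @export
bernstein <- function(q_hybrid, q_source_a, q_source_b) {
  if (any(q_source_a == q_source_b)) stop_param("sources have equal marker values")
  m <- (q_hybrid - q_source_b) / (q_source_a - q_source_b)
  clamped <- m < 0 | m > 1
  structure(mean(clamp01(m)), clamped = any(clamped))
}

#' PCA centroid-projection admixture estimator
#'
#' Projects each target individual orthogonally onto the line connecting
#' the two group centroids in a chosen 2-component PC plane; the
#' contribution of source A is one minus the distance of the projection to
#' the A centroid divided by the distance between centroids, clamped to
#' \[0, 1\].
#'
#' @param coords PCA coordinate matrix (individuals x components, row
#'   names = ids) or a `pca_result`.
#' @param group_a,group_b Ids of individuals defining the two centroids.
#' @param targets Ids of individuals to estimate.
#' @param components Which two components span the projection plane.
#' @return `data.frame(id, prop_a, prop_b, clamped)`.
#' @export
pca_projection_ancestry <- function(coords, group_a, group_b, targets,
                                    components = c(1, 2)) {
  if (inherits(coords, "pca_result")) coords <- coords$coordinates
  xy <- coords[, components, drop = FALSE]
  if (length(group_a) == 0 || length(group_b) == 0)
    stop_param("centroid groups must be non-empty")
  ca <- colMeans(xy[group_a, , drop = FALSE])
  cb <- colMeans(xy[group_b, , drop = FALSE])
  axis <- ca - cb
  len2 <- sum(axis^2)
  if (len2 == 0) stop_param("coincident centroids")
  res <- lapply(targets, function(id) {
    v <- xy[id, ] - cb
    t_ <- sum(v * axis) / len2          # 0 at centroid B, 1 at centroid A
    proj <- cb + t_ * axis
    prop <- 1 - sqrt(sum((proj - ca)^2)) / sqrt(len2)
    data.frame(id = id, prop_a = clamp01(prop), prop_b = 1 - clamp01(prop),
               clamped = prop < 0 | prop > 1)
  })
  do.call(rbind, res)
}

# patristic distance from node x to the point at distance h along the path
# from node g to node n (all distances measured along branches)
dist_to_path_point <- function(D, x, g, n, h) {
  t_ <- (D[x, g] + D[g, n] - D[x, n]) / 2   # where x's path meets the g-n path
  (D[x, g] - t_) + abs(t_ - h)
}

#' Tree-geometry admixture estimator on a TVD/NJ tree
#'
#' Uses the relative position of population attachment nodes on the NJ tree
#' of TVD distances. The "root" of a population is the internal node where
#' its pendant branch attaches (or the leaf itself with `node = "leaf"`).
#' The reference ratio is
#' `r = d(target_root, gog_root) / d(gog_root, angolan_midpoint)` with the
#' Angolan reference the midpoint of the path between the two Angolan
#' population roots, all distances patristic. With the default
#' `reading = "complement"` the Gulf-of-Guinea proportion is `1 - r` (so a
#' target coinciding with the Gulf-of-Guinea reference scores 1);
#' `reading = "literal"` returns `r` itself.
#'
#' @param tree A `phylo` tree whose tips include all four populations.
#' @param target Target population (tip label).
#' @param ref_gog Gulf-of-Guinea reference population (Yoruba role).
#' @param ref_ang_pair Two Angolan reference populations (Ganguela and
#'   Nyaneka roles).
#' @param reading `"complement"` (default) or `"literal"`.
#' @param node `"attachment"` (default) or `"leaf"`.
#' @return `data.frame(population, source, proportion, method)` with the
#'   two source rows; attribute `ratio` holds the raw ratio `r`.
#' @export
nj_geometry_ancestry <- function(tree, target, ref_gog, ref_ang_pair,
                                 reading = c("complement", "literal"),
                                 node = c("attachment", "leaf")) {
  reading <- match.arg(reading)
  node <- match.arg(node)
  tips <- c(target, ref_gog, ref_ang_pair)
  if (!all(tips %in% tree$tip.label)) stop_param("all four populations must be tree leaves")
  D <- ape::dist.nodes(tree)
  node_of <- function(lab) {
    tip <- match(lab, tree$tip.label)
    if (node == "leaf") return(tip)
    tree$edge[tree$edge[, 2] == tip, 1]   # attachment node
  }
  tn <- node_of(target); gn <- node_of(ref_gog)
  a1 <- node_of(ref_ang_pair[1]); a2 <- node_of(ref_ang_pair[2])
  h <- D[a1, a2] / 2
  d_ref <- dist_to_path_point(D, gn, a1, a2, h)
  if (d_ref == 0) stop_param("degenerate reference axis")
  r <- D[tn, gn] / d_ref
  if (r > 1.25) warning("target lies outside the reference axis (ratio > 1.25)")
  gog <- clamp01(if (reading == "complement") 1 - r else r)
  structure(data.frame(population = target,
                       source = c("gulf_of_guinea", "angola"),
                       proportion = c(gog, 1 - gog),
                       method = "nj_geometry"),
            ratio = r)
}
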