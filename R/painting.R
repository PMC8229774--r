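# Simplified Li-Stephens haplotype-copying engine. A recipient haplotype is
# modelled as a mosaic of segments copied from donor haplotypes: the hidden
# state at each site is the donor being copied, switches occur between
# adjacent sites with probability 1 - exp(-switch_scale) (uniform new donor),
# and the observed allele mismatches the donor allele with probability
# mis_copy. The forward-backward recursion uses per-site rescaling, which is
# algebraically exact and immune to underflow at any number of sites.

#' Copying-model parameters
#' @param switch_scale Expected ancestry-switch intensity per site interval
#'   (> 0); the per-interval switch probability is `1 - exp(-switch_scale)`.
#' @param mis_copy Per-site miscopy (emission error) probability, in (0, 0.5).
#' @return A `copying_params` object.
#' @export
copying_params <- function(switch_scale = 1e-2, mis_copy = 1e-3) {
  if (switch_scale <= 0) stop_param("switch_scale must be > 0")
  if (mis_copy <= 0 || mis_copy >= 0.5) stop_param("mis_copy must be in (0, 0.5)")
  structure(list(switch_scale = switch_scale, mis_copy = mis_copy),
            class = "copying_params")
}

# Scaled forward-backward over donor haplotypes for one recipient.
# Returns posterior state probabilities, expected distinct-donor chunk
# counts, expected copied lengths (in sites), expected switch events and
# mismatch emissions (for EM), and the data log-likelihood.
fb_paint <- function(recipient, donor_mat, params, want_gamma = FALSE) {
  D <- nrow(donor_mat); S <- ncol(donor_mat)
  if (D < 1) stop_param("need at least one donor haplotype")
  psw <- 1 - exp(-params$switch_scale)
  theta <- params$mis_copy
  # emission matrix D x S
  match <- donor_mat == matrix(recipient, nrow = D, ncol = S, byrow = TRUE)
  E <- ifelse(match, 1 - theta, theta)

  if (S == 1) {
    gam <- E[, 1] / sum(E[, 1])
    out <- list(chunk_counts = gam, chunk_lengths = gam, exp_switch = 0,
                exp_mismatch = sum(gam[!match[, 1]]),
                loglik = log(sum(E[, 1]) / D))
    if (want_gamma) out$gamma <- matrix(gam, ncol = 1)
    return(out)
  }

  a_hat <- matrix(0, D, S)   # scaled forward
  cs <- numeric(S)
  a <- E[, 1] / D
  cs[1] <- sum(a)
  a_hat[, 1] <- a / cs[1]
  for (s in 2:S) {
    a <- E[, s] * ((1 - psw) * a_hat[, s - 1] + psw / D)
    cs[s] <- sum(a)
    a_hat[, s] <- a / cs[s]
  }
  b_tl <- matrix(0, D, S)    # backward, scaled by the same constants
  b_tl[, S] <- 1
  for (s in (S - 1):1) {
    eb <- E[, s + 1] * b_tl[, s + 1]
    b_tl[, s] <- ((1 - psw) * eb + (psw / D) * sum(eb)) / cs[s + 1]
  }
  gamma1 <- a_hat[, 1] * b_tl[, 1]
  # chunk entries (initial state + switches into a *different* donor) and
  # EM sufficient statistics, accumulated over intervals
  entries <- gamma1
  exp_switch <- 0
  lengths <- numeric(D)
  exp_mismatch <- 0
  gam_prev <- gamma1
  lengths <- lengths + gam_prev
  exp_mismatch <- exp_mismatch + sum(gam_prev[!match[, 1]])
  for (s in 2:S) {
    gam <- a_hat[, s] * b_tl[, s]
    eb <- E[, s] * b_tl[, s]
    # P(switch event in interval s-1 -> s | data), including same-donor redraws
    exp_switch <- exp_switch + (psw / D) * sum(eb) / cs[s]
    # P(enter donor d from a different donor)
    entries <- entries + (psw / D) * eb * (1 - a_hat[, s - 1]) / cs[s]
    lengths <- lengths + gam
    exp_mismatch <- exp_mismatch + sum(gam[!match[, s]])
    gam_prev <- gam
  }
  out <- list(chunk_counts = entries, chunk_lengths = lengths,
              exp_switch = exp_switch, exp_mismatch = exp_mismatch,
              loglik = sum(log(cs)))
  if (want_gamma) out$gamma <- a_hat * b_tl
  out
}

# Viterbi donor path (used to cross-check expected chunk counts in the
# near-noiseless limit).
viterbi_paint <- function(recipient, donor_mat, params) {
  D <- nrow(donor_mat); S <- ncol(donor_mat)
  psw <- 1 - exp(-params$switch_scale)
  theta <- params$mis_copy
  match <- donor_mat == matrix(recipient, nrow = D, ncol = S, byrow = TRUE)
  logE <- ifelse(match, log1p(-theta), log(theta))
  v <- logE[, 1] - log(D)
  back <- matrix(0L, D, S)
  for (s in 2:S) {
    stay <- v + log(1 - psw + psw / D)
    jump <- max(v) + log(psw / D)
    new_v <- pmax(stay, jump)
    back[, s] <- ifelse(stay >= jump, seq_len(D), which.max(v))
    v <- new_v + logE[, s]
  }
  path <- integer(S)
  path[S] <- which.max(v)
  for (s in S:2) path[s - 1] <- back[path[s], s]
  path
}

#' Paint one recipient haplotype against a donor panel
#'
#' Computes, by the forward-backward recursion, the expected number of
#' copied chunks (distinct-donor segment entries; the initial state counts
#' as one) and expected copied length contributed by every donor haplotype.
#'
#' @param recipient 0/1 haplotype vector.
#' @param donors 0/1 donor haplotype matrix (haplotypes in rows), or a
#'   `hap_panel`.
#' @param params A [copying_params()].
#' @return List with `chunk_counts`, `chunk_lengths` (per donor), and
#'   `loglik`. Chunk counts sum to the expected total segment count (>= 1).
#' @export
paint <- function(recipient, donors, params = copying_params()) {
  donor_mat <- if (inherits(donors, "hap_panel")) donors$haps else as.matrix(donors)
  if (nrow(donor_mat) == 0) stop_param("zero donors")
  fb <- fb_paint(recipient, donor_mat, params)
  fb[c("chunk_counts", "chunk_lengths", "loglik")]
}

#' Estimate copying parameters by EM
#'
#' Runs the specified number of EM iterations of the switch and miscopy
#' parameters, pooling expected switch counts and mismatch emissions over
#' recipients and chromosomes. Per-chromosome estimates are weighted by SNP
#' count through the pooling, and each recipient haplotype is painted
#' against the haplotypes of all *other* individuals. The data
#' log-likelihood is checked to be non-decreasing across iterations.
#'
#' @param panel A `hap_panel`.
#' @param n_em_iter Number of EM iterations.
#' @param subset Chromosomes to use (default: all in the panel).
#' @param init Starting [copying_params()].
#' @param recipients Optional individual ids to paint (default: all).
#' @return A `copying_params` with attributes `loglik_trace` and `n_snps`.
#' @export
estimate_copying_params <- function(panel, n_em_iter = 10, subset = NULL,
                                    init = copying_params(),
                                    recipients = NULL) {
  chroms <- subset %||% unique(panel$sites$chrom)
  if (length(chroms) == 0) stop_param("empty chromosome subset")
  ids <- unique(panel$individual)
  rec_ids <- recipients %||% ids
  params <- init
  trace <- numeric(n_em_iter)
  total_snps <- sum(panel$sites$chrom %in% chroms)
  for (iter in seq_len(n_em_iter)) {
    tot_switch <- 0; tot_mismatch <- 0; tot_intervals <- 0; tot_sites <- 0
    ll <- 0
    for (ch in chroms) {
      cols <- which(panel$sites$chrom == ch)
      if (length(cols) < 2) next
      for (id in rec_ids) {
        rec_rows <- which(panel$individual == id)
        don_rows <- which(panel$individual != id)
        for (r in rec_rows) {
          fb <- fb_paint(panel$haps[r, cols],
                         panel$haps[don_rows, cols, drop = FALSE], params)
          tot_switch <- tot_switch + fb$exp_switch
          tot_mismatch <- tot_mismatch + fb$exp_mismatch
          tot_intervals <- tot_intervals + (length(cols) - 1)
          tot_sites <- tot_sites + length(cols)
          ll <- ll + fb$loglik
        }
      }
    }
    trace[iter] <- ll
    if (iter > 1 && ll < trace[iter - 1] - 1e-8)
      stop("internal error: EM log-likelihood decreased")
    psw <- min(max(tot_switch / tot_intervals, 1e-9), 1 - 1e-9)
    theta <- min(max(tot_mismatch / tot_sites, 1e-9), 0.5 - 1e-9)
    params <- copying_params(switch_scale = -log(1 - psw), mis_copy = theta)
  }
  attr(params, "loglik_trace") <- trace
  attr(params, "n_snps") <- total_snps
  params
}

#' Coancestry matrix from haplotype painting
#'
#' Paints every recipient individual (both haplotypes, chromosome by
#' chromosome) against a donor panel and aggregates expected chunk counts to
#' donor populations. In `all_vs_all` mode every individual is a recipient
#' and the donors are all haplotypes of *other* individuals (the self
#' diagonal is structurally zero). In `donor_recipient` mode the recipient
#' and donor population sets must be disjoint.
#'
#' @param panel A `hap_panel`.
#' @param mode `"all_vs_all"` or `"donor_recipient"`.
#' @param donor_set,recipient_set Population labels (donor_recipient mode).
#' @param params A [copying_params()].
#' @return A `coancestry` object: `chunk_counts` (recipient individuals x
#'   donor groups), `pop_profiles` (recipient populations x donor groups;
#'   average of the row-normalized individual profiles), `mode`.
#' @export
coancestry <- function(panel, mode = c("all_vs_all", "donor_recipient"),
                       donor_set = NULL, recipient_set = NULL,
                       params = copying_params()) {
  mode <- match.arg(mode)
  ids <- unique(panel$individual)
  pop_of <- panel$pop[match(ids, panel$individual)]
  names(pop_of) <- ids
  if (mode == "donor_recipient") {
    if (is.null(donor_set) || is.null(recipient_set))
      stop_param("donor_set and recipient_set required in donor_recipient mode")
    if (length(intersect(donor_set, recipient_set)) > 0)
      stop_param("donor and recipient sets must be disjoint")
    rec_ids <- ids[pop_of %in% recipient_set]
    don_rows_all <- which(panel$pop %in% donor_set)
    donor_groups <- sort(unique(panel$pop[don_rows_all]))
    if (length(rec_ids) == 0) stop_param("no recipients found")
    if (length(don_rows_all) == 0) stop_param("recipient with no donors")
  } else {
    rec_ids <- ids
    donor_groups <- ids   # per-individual donors in all-vs-all mode
  }
  chroms <- unique(panel$sites$chrom)
  cc <- matrix(0, nrow = length(rec_ids), ncol = length(donor_groups),
               dimnames = list(rec_ids, donor_groups))
  for (id in rec_ids) {
    if (mode == "all_vs_all") {
      don_rows <- which(panel$individual != id)
      agg_by <- panel$individual[don_rows]
    } else {
      don_rows <- don_rows_all
      agg_by <- panel$pop[don_rows]
    }
    rec_rows <- which(panel$individual == id)
    for (ch in chroms) {
      cols <- which(panel$sites$chrom == ch)
      for (r in rec_rows) {
        fb <- fb_paint(panel$haps[r, cols],
                       panel$haps[don_rows, cols, drop = FALSE], params)
        agg <- tapply(fb$chunk_counts, agg_by, sum)
        cc[id, names(agg)] <- cc[id, names(agg)] + agg
      }
    }
  }
  prof <- cc / rowSums(cc)
  rec_pops <- pop_of[rec_ids]
  pop_profiles <- do.call(rbind, lapply(sort(unique(rec_pops)), function(p) {
    colMeans(prof[rec_pops == p, , drop = FALSE])
  }))
  rownames(pop_profiles) <- sort(unique(rec_pops))
  structure(list(chunk_counts = cc, pop_profiles = pop_profiles,
                 recipient_pops = rec_pops, mode = mode),
            class = "coancestry")
}

#' Write a coancestry matrix as TSV (recipient rows, donor columns)
#' @param cm A `coancestry` object.
#' @param path Output path.
#' @export
write_coancestry <- function(cm, path) {
  utils::write.table(cm$chunk_counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
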