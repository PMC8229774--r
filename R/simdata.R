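# Synthetic-data generators. Every generator is a pure function of
# (parameters, seed): identical calls return bit-identical objects.

#' Draw source-population allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies are uniform on \[0.05, 0.95\] (bounded away from
#' fixation so that synthetic sites are segregating); each source population
#' draws its site frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `F` is the per-source differentiation
#' parameter.
#'
#' @param n_sites Number of SNPs.
#' @param fst_per_source Vector of Balding-Nichols `F` values, one per
#'   source, each in (0, 1).
#' @param seed Integer seed.
#' @param anc_range Range of the uniform ancestral frequency draw.
#' @return A `source_frequencies` object with fields `freq`
#'   (sources x sites), `anc_freq`, `fst`, `n_sites`, `n_sources`.
#' @export
sample_source_frequencies <- function(n_sites, fst_per_source, seed = 1,
                                      anc_range = c(0.05, 0.95)) {
  if (n_sites < 1) stop_param("n_sites must be >= 1")
  f <- as.numeric(fst_per_source)
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop_param("each fst must be finite and in (0, 1)")
  with_seed(seed, {
    p <- stats::runif(n_sites, anc_range[1], anc_range[2])
    freq <- matrix(0, nrow = length(f), ncol = n_sites)
    for (k in seq_along(f)) {
      s <- (1 - f[k]) / f[k]
      freq[k, ] <- stats::rbeta(n_sites, p * s, (1 - p) * s)
    }
    structure(list(freq = freq, anc_freq = p, fst = f,
                   n_sites = n_sites, n_sources = length(f)),
              class = "source_frequencies")
  })
}

#' Hudson Fst from genotype allele counts of two populations
#'
#' Ratio-of-averages estimator with the standard finite-sample correction:
#' per-site numerator `(pa-pb)^2 - pa(1-pa)/(na-1) - pb(1-pb)/(nb-1)` and
#' denominator `pa(1-pb) + pb(1-pa)`, where `na`, `nb` are sampled allele
#' counts. Used internally by [calibrate_fst()]; the user-facing entry point
#' on a `genotype_matrix` is [hudson_fst()].
#' @keywords internal
hudson_fst_counts <- function(pa, na_, pb, nb_) {
  ok <- na_ > 1 & nb_ > 1
  pa <- pa[ok]; pb <- pb[ok]; na_ <- na_[ok]; nb_ <- nb_[ok]
  num <- (pa - pb)^2 - pa * (1 - pa) / (na_ - 1) - pb * (1 - pb) / (nb_ - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  keep <- den > 0
  list(fst = sum(num[keep]) / sum(den[keep]), num = num, den = den)
}

#' Calibrate the Balding-Nichols F to a target Hudson Fst
#'
#' Bisection on `F` with Monte-Carlo evaluation: at each candidate `F`, pairs
#' of populations are simulated (frequencies, then binomial allele counts at
#' the given sample sizes) and the mean Hudson Fst compared to the target.
#'
#' @param target_fst Target Hudson Fst, in (0, 0.5).
#' @param n_sites Sites per Monte-Carlo replicate (>= 1e5 recommended).
#' @param sample_sizes Diploid sample sizes of the two populations.
#' @param seed Integer seed.
#' @param n_reps Monte-Carlo replicates per evaluation.
#' @param tol Relative tolerance on the achieved mean Fst.
#' @return The calibrated `F` (numeric scalar) with attribute
#'   `achieved_fst`.
#' @export
calibrate_fst <- function(target_fst, n_sites = 1e5, sample_sizes = c(9, 8),
                          seed = 1, n_reps = 3, tol = 0.05) {
  if (!is.finite(target_fst) || target_fst < 0 || target_fst >= 0.5)
    stop_param("target_fst must be in [0, 0.5)")
  if (target_fst == 0) return(structure(1e-6, achieved_fst = 0))
  n_sites <- max(n_sites, 1e5)  # stabilize the Monte-Carlo evaluation
  evaluate <- function(F, s) {
    mean(vapply(seq_len(n_reps), function(r) {
      sf <- sample_source_frequencies(n_sites, c(F, F),
                                      seed = derive_seed(s, paste0("cal", r)))
      with_seed(derive_seed(s, paste0("cnt", r)), {
        na_ <- 2 * sample_sizes[1]; nb_ <- 2 * sample_sizes[2]
        pa <- stats::rbinom(n_sites, na_, sf$freq[1, ]) / na_
        pb <- stats::rbinom(n_sites, nb_, sf$freq[2, ]) / nb_
        hudson_fst_counts(pa, rep(na_, n_sites), pb, rep(nb_, n_sites))$fst
      })
    }, numeric(1)))
  }
  lo <- 1e-6; hi <- 0.45
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    got <- evaluate(mid, derive_seed(seed, paste0("bis", it)))
    if (abs(got - target_fst) / target_fst <= tol / 2) {
      return(structure(mid, achieved_fst = got))
    }
    if (got < target_fst) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  got <- evaluate(mid, derive_seed(seed, "final"))
  if (abs(got - target_fst) / target_fst > tol)
    stop_param("calibration failed: target %.4g, achieved %.4g (F = %.4g)",
               target_fst, got, mid)
  structure(mid, achieved_fst = got)
}

#' Admixture specification for one synthetic population
#'
#' @param label Population label.
#' @param proportions Ancestry proportions over sources (sum to 1).
#' @param n_individuals Number of diploids.
#' @return An `admixture_spec` object.
#' @export
admixture_spec <- function(label, proportions, n_individuals) {
  proportions <- as.numeric(proportions)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop_param("proportions must be nonnegative and sum to 1")
  structure(list(label = label, proportions = proportions,
                 n_individuals = as.integer(n_individuals)),
            class = "admixture_spec")
}

# Default site metadata: sites laid contiguously over autosomes 1..22,
# uniform spacing. ref/alt drawn uniformly over ordered nucleotide pairs
# (so Ti/Tv of random synthetic sites is 4/8 = 0.5).
default_sites <- function(n_sites, spacing = 2000L, n_chrom = 22L) {
  per <- ceiling(n_sites / n_chrom)
  chrom <- rep(as.character(seq_len(n_chrom)), each = per)[seq_len(n_sites)]
  pos <- unlist(lapply(rle(chrom)$lengths, function(l) seq_len(l) * spacing))
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt))
}

#' Simulate admixed diploid genotypes
#'
#' Each allele copy of each individual is independently assigned a source
#' population according to the individual's ancestry proportions, then drawn
#' `Bernoulli(freq[source, site])`. True per-individual ancestry dosages are
#' attached as attribute `truth` (individuals x sources, mean source
#' assignment over allele copies).
#'
#' @param freqs A `source_frequencies` object.
#' @param specs List of [admixture_spec()]s.
#' @param seed Integer seed.
#' @param spacing Inter-SNP spacing in bp for the generated site map.
#' @return A `genotype_matrix` with attribute `truth`.
#' @export
simulate_admixed_genotypes <- function(freqs, specs, seed = 1, spacing = 2000L) {
  if (inherits(specs, "admixture_spec")) specs <- list(specs)
  K <- freqs$n_sources; S <- freqs$n_sites
  for (sp in specs)
    if (length(sp$proportions) != K)
      stop_param("spec '%s' has %d proportions for %d sources",
                 sp$label, length(sp$proportions), K)
  with_seed(seed, {
    sites <- default_sites(S, spacing)
    n_tot <- sum(vapply(specs, function(s) s$n_individuals, integer(1)))
    dos <- matrix(0L, nrow = n_tot, ncol = S)
    truth <- matrix(0, nrow = n_tot, ncol = K)
    ids <- character(n_tot); pops <- character(n_tot)
    row <- 0
    for (sp in specs) {
      for (i in seq_len(sp$n_individuals)) {
        row <- row + 1
        ids[row] <- sprintf("%s_%02d", sp$label, i)
        pops[row] <- sp$label
        src1 <- sample.int(K, S, replace = TRUE, prob = sp$proportions)
        src2 <- sample.int(K, S, replace = TRUE, prob = sp$proportions)
        a1 <- stats::rbinom(S, 1, freqs$freq[cbind(src1, seq_len(S))])
        a2 <- stats::rbinom(S, 1, freqs$freq[cbind(src2, seq_len(S))])
        dos[row, ] <- a1 + a2
        truth[row, ] <- (tabulate(src1, K) + tabulate(src2, K)) / (2 * S)
      }
    }
    g <- genotype_matrix(dos, sites, data.frame(id = ids, pop = pops))
    attr(g, "truth") <- truth
    g
  })
}

#' Simulate phased haplotype mosaics with known ancestry tracks
#'
#' Recipient haplotypes are built by copying from donor haplotypes: ancestry
#' switch points occur independently at each inter-site interval with
#' probability `switch_rate`; at each switch a source is drawn by
#' `proportions` and a donor haplotype uniformly within that source.
#'
#' @param source_haps Named list of 0/1 haplotype matrices, one per source
#'   (haplotypes in rows), all over the same sites.
#' @param proportions Source proportions (sum to 1).
#' @param switch_rate Per-interval switch probability, in (0, 1).
#' @param n_recipients Number of recipient haplotypes.
#' @param seed Integer seed.
#' @param mis_copy Per-site miscopy (emission error) probability.
#' @return List with `haps` (recipients x sites), `tracks` (a list per
#'   recipient of `data.frame(start, end, source, donor)`), and `n_switches`.
#' @export
simulate_haplotype_mosaic <- function(source_haps, proportions, switch_rate,
                                      n_recipients, seed = 1, mis_copy = 0) {
  if (switch_rate <= 0 || switch_rate >= 1) stop_param("switch_rate must be in (0,1)")
  if (any(vapply(source_haps, nrow, integer(1)) < 2))
    stop_param("need at least 2 haplotypes per source")
  K <- length(source_haps)
  S <- ncol(source_haps[[1]])
  with_seed(seed, {
    haps <- matrix(0L, n_recipients, S)
    tracks <- vector("list", n_recipients)
    n_switches <- integer(n_recipients)
    for (r in seq_len(n_recipients)) {
      sw <- which(stats::runif(S - 1) < switch_rate)
      breaks <- c(1L, sw + 1L)
      ends <- c(sw, S)
      n_switches[r] <- length(sw)
      src <- sample.int(K, length(breaks), replace = TRUE, prob = proportions)
      don <- vapply(src, function(k) sample.int(nrow(source_haps[[k]]), 1), integer(1))
      h <- integer(S)
      for (seg in seq_along(breaks)) {
        idx <- breaks[seg]:ends[seg]
        h[idx] <- source_haps[[src[seg]]][don[seg], idx]
      }
      if (mis_copy > 0) {
        flip <- stats::runif(S) < mis_copy
        h[flip] <- 1L - h[flip]
      }
      haps[r, ] <- h
      tracks[[r]] <- data.frame(start = breaks, end = ends,
                                source = src, donor = don)
    }
    list(haps = haps, tracks = tracks, n_switches = n_switches)
  })
}

#' Simulate a cohort containing one labelled parent-offspring duo
#'
#' The parent and all unrelated individuals are drawn from the source-1
#' Balding-Nichols frequencies; at each site the offspring receives one of
#' the parent's two alleles (uniform pick) and one allele from the population
#' frequency. With `clone = TRUE` the "offspring" is an exact copy of the
#' parent instead (useful as a self-comparison fixture).
#'
#' @param freqs A `source_frequencies` object (source 1 is used).
#' @param n_unrelated Number of additional unrelated individuals.
#' @param seed Integer seed.
#' @param clone Duplicate the parent instead of simulating transmission.
#' @return A `genotype_matrix`; the duo has ids `parent` and `offspring`.
#' @export
simulate_duo <- function(freqs, n_unrelated = 0, seed = 1, clone = FALSE) {
  S <- freqs$n_sites
  if (S < 1000) stop_param("need >= 1000 sites for a stable kinship fixture")
  p <- freqs$freq[1, ]
  with_seed(seed, {
    pa1 <- stats::rbinom(S, 1, p); pa2 <- stats::rbinom(S, 1, p)
    if (clone) {
      off <- pa1 + pa2
    } else {
      pick <- stats::runif(S) < 0.5
      off <- ifelse(pick, pa1, pa2) + stats::rbinom(S, 1, p)
    }
    dos <- rbind(pa1 + pa2, off)
    ids <- c("parent", "offspring")
    if (n_unrelated > 0) {
      unrel <- t(vapply(seq_len(n_unrelated),
                        function(i) stats::rbinom(S, 2, p), numeric(S)))
      dos <- rbind(dos, unrel)
      ids <- c(ids, sprintf("unrel_%02d", seq_len(n_unrelated)))
    }
    genotype_matrix(dos, default_sites(S),
                    data.frame(id = ids, pop = rep("duo_pop", length(ids))))
  })
}

#' Y-STR dataset constructor
#' @param haplotypes Integer matrix, haplotypes in rows, loci in columns.
#' @param loci Ordered locus names.
#' @param labels Population label per haplotype.
#' @return A `ystr_dataset`.
#' @export
ystr_dataset <- function(haplotypes, loci, labels) {
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != length(loci))
    stop_param("haplotypes have %d loci but %d names given", ncol(haplotypes), length(loci))
  if (any(haplotypes < 1) || any(haplotypes != round(haplotypes)))
    stop_param("repeat counts must be positive integers")
  colnames(haplotypes) <- loci
  structure(list(loci = loci, haplotypes = haplotypes,
                 labels = as.character(labels)), class = "ystr_dataset")
}

# one single-step mutation, reflecting at repeat count 1
mutate_ystr <- function(hap, n_mut) {
  if (n_mut == 0) return(hap)
  loci <- sample.int(length(hap), n_mut, replace = TRUE)
  steps <- sample(c(-1L, 1L), n_mut, replace = TRUE)
  for (m in seq_len(n_mut)) {
    x <- hap[loci[m]] + steps[m]
    hap[loci[m]] <- if (x < 1) hap[loci[m]] + 1L else x  # reflect off the floor
  }
  hap
}

#' Simulate Y-STR haplotypes on a star or Wright-Fisher genealogy
#'
#' Star mode: each sampled lineage independently accumulates
#' `Poisson(L * mu * generations)` single-step mutations (+-1 repeat, equal
#' probability, locus uniform; counts reflect at 1). Wright-Fisher mode: a
#' constant male population of `n_lineages` descends from the founder; each
#' generation sons pick fathers with probability proportional to mating
#' success, where a fixed dominant class of size `ceiling(d * N)` has success
#' multiplied by `b` and is refilled with fidelity `tau` from sons of
#' dominant fathers (lineage-carrying sons first); haplotypes mutate per
#' locus per generation at rate `mu`.
#'
#' @param mode `"star"` or `"wright_fisher"`.
#' @param founder Integer repeat-count vector for the founding haplotype.
#' @param generations Number of generations (may be fractional in star mode).
#' @param mu Mutation rate per locus per generation, in (0, 0.1).
#' @param n_lineages Sampled lineages (star) or male population size (WF).
#' @param dominance Optional [dominance_model()] (WF mode only).
#' @param seed Integer seed.
#' @param loci Locus names.
#' @param sample_n In WF mode, number of final-generation males sampled
#'   (default all).
#' @return A `ystr_dataset`. Star mode attaches attribute `n_mutations`;
#'   WF mode attaches `lineage_freq` (per-generation carrier frequency) and
#'   `lineage` (carrier status of the sampled males).
#' @export
simulate_ystr <- function(mode = c("star", "wright_fisher"), founder, generations,
                          mu = 0.0025, n_lineages, dominance = NULL, seed = 1,
                          loci = paste0("DYS", seq_along(founder)),
                          sample_n = NULL) {
  mode <- match.arg(mode)
  if (mu <= 0 || mu >= 0.1) stop_param("mu must be in (0, 0.1)")
  if (generations < 0) stop_param("generations must be >= 0")
  if (length(founder) != length(loci))
    stop_param("founder length does not match loci")
  L <- length(founder)
  founder <- as.integer(founder)
  with_seed(seed, {
    if (mode == "star") {
      n_mut <- stats::rpois(n_lineages, L * mu * generations)
      haps <- t(vapply(n_mut, function(m) mutate_ystr(founder, m), integer(L)))
      out <- ystr_dataset(haps, loci, rep("star", n_lineages))
      attr(out, "n_mutations") <- n_mut
      return(out)
    }
    # Wright-Fisher with optional heritable dominance
    N <- n_lineages
    haps <- matrix(rep(founder, each = N), nrow = N)
    d <- if (is.null(dominance)) 0 else dominance$d
    b <- if (is.null(dominance)) 1 else dominance$b
    tau <- if (is.null(dominance)) 0 else dominance$tau
    n_dom <- if (d > 0) as.integer(ceiling(d * N)) else 0L
    dom <- c(rep(TRUE, n_dom), rep(FALSE, N - n_dom))
    p0 <- if (is.null(dominance)) 0 else dominance$p0
    q0 <- if (is.null(dominance)) 1 else dominance$q0
    n_lin <- round(p0 * N)
    n_lin_dom <- min(n_dom, round(q0 * n_dom))
    lineage <- rep(FALSE, N)
    if (n_lin_dom > 0) lineage[seq_len(n_lin_dom)] <- TRUE
    extra <- n_lin - n_lin_dom
    if (extra > 0) lineage[n_dom + seq_len(extra)] <- TRUE
    freq_track <- numeric(floor(generations) + 1)
    freq_track[1] <- mean(lineage)
    for (t in seq_len(floor(generations))) {
      w <- ifelse(dom, b, 1)
      fathers <- sample.int(N, N, replace = TRUE, prob = w)
      haps <- haps[fathers, , drop = FALSE]
      lineage <- lineage[fathers]
      father_dom <- dom[fathers]
      n_mut <- stats::rpois(N, L * mu)
      mut_rows <- which(n_mut > 0)
      for (i in mut_rows) haps[i, ] <- mutate_ystr(haps[i, ], n_mut[i])
      if (n_dom > 0) {
        # refill the dominant class: tau*n_dom slots from sons of dominant
        # fathers (lineage sons first), the rest uniformly at random
        new_dom <- rep(FALSE, N)
        slots_dom <- min(round(tau * n_dom), sum(father_dom))
        cand <- order(!(father_dom & lineage), !father_dom, stats::runif(N))
        picked <- cand[seq_len(slots_dom)]
        new_dom[picked] <- TRUE
        remaining <- setdiff(seq_len(N), picked)
        fill <- sample(remaining, n_dom - slots_dom)
        new_dom[fill] <- TRUE
        dom <- new_dom
      }
      freq_track[t + 1] <- mean(lineage)
    }
    take <- if (is.null(sample_n)) seq_len(N) else sample.int(N, sample_n)
    out <- ystr_dataset(haps[take, , drop = FALSE], loci,
                        rep("wf", length(take)))
    attr(out, "lineage_freq") <- freq_track
    attr(out, "lineage") <- lineage[take]
    out
  })
}

#' Simulate short aligned sequences from a root sequence
#'
#' Each of `n` sequences mutates independently: every position changes with
#' probability `subs_rate`, to a uniformly chosen different base.
#'
#' @param root Root nucleotide string over A/C/G/T.
#' @param n Number of sequences.
#' @param subs_rate Per-site substitution probability in \[0, 1).
#' @param seed Integer seed.
#' @return Named character vector of sequences, with attribute
#'   `segregating_sites`.
#' @export
simulate_sequences <- function(root, n, subs_rate, seed = 1) {
  root <- toupper(root)
  if (nchar(root) == 0) stop_param("root sequence is empty")
  chars <- strsplit(root, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop_param("invalid characters in root sequence")
  nts <- c("A", "C", "G", "T")
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      s <- chars
      hit <- which(stats::runif(length(s)) < subs_rate)
      for (j in hit) s[j] <- sample(setdiff(nts, s[j]), 1)
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("seq_%03d", seq_len(n))
    m <- do.call(rbind, strsplit(seqs, ""))
    seg <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
    attr(seqs, "segregating_sites") <- seg
    seqs
  })
}

#' Write sequences to FASTA
#' @param seqs Named character vector (as from [simulate_sequences()]).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  names(bin) <- names(seqs)
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  vapply(as.character(bin), function(x) toupper(paste(x, collapse = "")), character(1))
}

#' Write a Y-STR table (TSV: sample_id, population, one column per locus)
#' @param ystr A `ystr_dataset`.
#' @param path Output path.
#' @export
write_ystr <- function(ystr, path) {
  df <- data.frame(sample_id = sprintf("y_%03d", seq_len(nrow(ystr$haplotypes))),
                   population = ystr$labels)
  df <- cbind(df, as.data.frame(ystr$haplotypes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Y-STR table written by [write_ystr()]
#' @param path TSV path.
#' @export
read_ystr <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  loci <- setdiff(colnames(df), c("sample_id", "population"))
  ystr_dataset(as.matrix(df[, loci, drop = FALSE]), loci, df$population)
}
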