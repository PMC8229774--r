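---
title: "Models and methods behind maroongen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind maroongen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maroongen)
```

`maroongen` packages the population-genomic toolkit needed to study small,
recently founded admixed populations — the motivating case being the creole-
and maroon-descended communities of the Gulf of Guinea islands, whose gene
pools mix European, Gulf-of-Guinea (Nigeria/Benin) and Congo/Angola sources
and, in the maroon isolate, carry the signature of a socially selected
Y-chromosome lineage. Every analysis is exercisable end to end on synthetic
data with known ground truth, so the behaviour of each estimator can be
audited before it is pointed at real genotypes.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
emulate.

## The synthetic cohort generator

Source populations are modelled with **Balding–Nichols differentiation**: an
ancestral allele frequency $p$ is drawn uniformly on $[0.05, 0.95]$ and each
source $k$ draws its site frequency from
$\mathrm{Beta}\!\big(p\,(1-F_k)/F_k,\ (1-p)(1-F_k)/F_k\big)$, so $F_k$
controls how far source $k$ has drifted from the shared ancestor. The
ancestral frequencies are bounded away from fixation because the downstream
analyses operate on segregating SNPs only; an unbounded draw would waste a
large fraction of sites on monomorphic positions.

Admixed diploids assign each allele copy independently to a source according
to the individual's ancestry proportions and then draw the allele
Bernoulli from that source's frequency. The realized per-individual source
assignments are returned as ground truth, and a regression of realized on
specified proportions has slope 1 within 2% at 150k sites (tested).

The defaults used throughout the examples and the acceptance analyses are
chosen to mimic the study system: three sources with $F = 0.16$ for Europe
and $F = 0.03$ for each of the two African sources (an isosceles source
triangle — the two African sources are symmetric about the European one,
which makes the centroid-projection estimator geometrically unbiased),
cohorts of 7–12 diploids, and ~150,000 SNPs, the scale of an expanded-exome
SNP set. Where a published pairwise differentiation must be met exactly,
`calibrate_fst()` bisects on $F$ with a Monte-Carlo evaluation of the
realized Hudson Fst at the target sample sizes; the calibration absorbs the
mapping between the model parameter and the estimator, whatever its exact
form.

Because no demographic history for the island populations is published, the
generator is calibrated to reproduce printed summary statistics (Fst,
ancestry fractions) rather than an explicit history; it does not emulate
linkage disequilibrium decay along real recombination maps, ascertainment
of exome capture, or background selection. Tests that pass on these data
therefore validate the estimators' statistical behaviour, not the realism
of any particular demographic scenario.

**Y-STR genealogies.** Star mode gives each sampled lineage an independent
$\mathrm{Poisson}(L \mu g)$ number of strictly single-step ($\pm 1$ repeat,
equal probability, locus uniform) mutations — the model under which the
rho statistic is calibrated. Repeat counts reflect off a floor of 1, since
they are physical copy numbers. Wright–Fisher mode holds the male
population constant; sons choose fathers proportionally to mating success,
a fixed dominant class of size $\lceil dN \rceil$ has success multiplied by
$b$, and the class is refilled each generation with fidelity $\tau$ from
sons of dominant fathers (lineage-carrying sons first, ties broken by a
seeded shuffle). Multi-step microsatellite mutations are deliberately
ignored, consistent with the single-step calibration of the rho statistic.

Every generator is a pure function of its parameters and seed; repeated
calls are bit-identical, and the RNG state of the caller is never
perturbed.

## Variant and sample quality control

`filter_sites()` fixes the order of operations: non-autosomal and
non-biallelic sites first, then removal of sites at or above the mean-depth
ceiling (35×), then genotype-level masking (depth < 3 or quality < 20
becomes missing), and only then the site missingness rule (> 15%). Masking
precedes the missingness rule deliberately — a low-quality genotype counts
as missing — and the whole filter is idempotent. "Autosomal" accepts both
`1`–`22` and `chr1`–`chr22` chromosome dialects.

The Hardy–Weinberg test is the exact conditional test: given the allele
counts, the p-value sums the probabilities of all heterozygote
configurations no more probable than the observed one (two-sided; a
one-sided heterozygote-deficit variant was considered and not adopted, as
nothing in the filtering protocol being mirrored indicates sidedness).
Monomorphic sites return $p = 1$ by convention — there is nothing to
reject. The population-level filter removes a site only when it fails in at
least two populations, which keeps single-population drift or genotyping
quirks from deleting sites genome-wide.

Kinship uses the KING-robust within-pair estimator
$\varphi = (N_{Aa,Aa} - 2 N_{AA,aa}) / (N_{Aa}^{(i)} + N_{Aa}^{(j)})$,
which is robust to population structure because it never references
population allele frequencies. Self-comparison gives 0.5, parent–offspring
0.25 in expectation, unrelateds 0. Pruning is greedy — repeatedly drop the
individual involved in most pairs above threshold, ties broken by higher
missingness then id — with the threshold defaulting to 0.177, the
conventional first/second-degree boundary (the protocol being mirrored
reports removing one member of a 0.248 pair but not its threshold).

## The haplotype-copying (chromosome painting) engine

A recipient haplotype is modelled as a mosaic copied from donor
haplotypes. The hidden state at each site is the donor being copied; the
state switches between adjacent sites with probability
$1 - e^{-\lambda}$ (`switch_scale` $\lambda$, uniform re-draw of the new
donor within the donor set), and the observed allele differs from the donor
allele with probability $\theta$ (`mis_copy`). Sites are treated as evenly
spaced: the data this mirrors are exome-capture SNPs without a usable
fine-scale genetic map, so a per-interval switch probability is the honest
parameterization.

The forward–backward recursion is computed with per-site rescaling, which
is algebraically exact and keeps every quantity in the unit range at any
number of sites; posterior site marginals sum to one within $10^{-9}$
(asserted in tests). The low-rank structure of the transition matrix
(uniform redraw) makes each sweep $O(S \cdot D)$.

The "chunk count" credited to donor $d$ is the expected number of entries
into state $d$ from a *different* donor, plus the initial-state posterior —
so a single donor always yields exactly one chunk, and re-draws of the same
donor do not create spurious segment boundaries. In the limit
$\theta \ll \lambda \to 0$ on noiseless mosaics the expected counts
converge to the Viterbi segment count (tested on 100-site toys).

EM updates for $(\lambda, \theta)$ pool expected switch events and mismatch
emissions over recipients and chromosomes (chromosome contributions are
weighted by their SNP counts through the pooling) and are guaranteed
monotone in the data log-likelihood; a decrease beyond $10^{-8}$ aborts as
an internal error. Starting values default to $\lambda = 10^{-2}$,
$\theta = 10^{-3}$; parameter recovery within a factor of two at 10k sites
is tested, as is insensitivity of the monotonicity to the start.

Coancestry matrices aggregate per-donor chunk counts to donor populations.
In all-vs-all mode each individual is painted against all haplotypes of all
*other* individuals (the self-diagonal is structurally zero); in
donor/recipient mode the two sets must be disjoint. A population's copy
profile is the average of the row-normalized profiles of its members.

## Ancestry geometry: TVD, Neighbor-Joining, and three estimators

Differences between copy profiles are measured by total variation distance,
$\mathrm{TVD}(x, y) = \tfrac12 \sum_k |x_k - y_k|$ — a metric on the
probability simplex (axioms property-tested on $10^4$ random profiles).
Trees are built with Saitou–Nei Neighbor-Joining; additive matrices are
recovered exactly, and negative branch lengths (possible under noise) are
truncated to zero with the deficit moved to the sibling branch so path
lengths through the parent are preserved. Split support comes from
resampling individuals with replacement within populations and counting the
fraction of replicate trees containing each split.

Three admixture-proportion estimators are provided:

* **Bernstein interpolation** of an ancestry-component frequency between
  two source values, per component, averaged with equal weights when two
  marker components are supplied (the combination rule is unspecified in
  the protocol being mirrored; equal weighting is the neutral choice).
* **PCA centroid projection**: orthogonal projection of each target onto
  the line joining two group centroids in a chosen two-PC plane; the
  contribution of source A is one minus the distance from the projection to
  the A centroid over the centroid separation, clamped to $[0,1]$ with
  clamping recorded. The two axes (European vs African; Gulf-of-Guinea vs
  Angolan) are estimated independently, mirroring the two separate
  projections of the original analysis. In the three-source synthetic
  world the intra-African axis appears on PC2 (the real panel's many
  African populations push it to PC3); the function takes the component
  pair as an argument.
* **NJ tree geometry**: with profile mixtures along a line, TVD distances
  are proportional to differences in the mixture coefficient and NJ
  reconstructs the line exactly, so the patristic position of a
  population's attachment node between the Gulf-of-Guinea reference and the
  midpoint of the two Angolan references reads off its ancestry. Distances
  are patristic (along branches) — the published description says
  "Euclidean" on a drawn tree, but a 2-D embedding is renderer-dependent,
  so the along-branch reading is the reproducible one. The printed formula
  assigns the ratio itself to the Gulf-of-Guinea contribution, yet the
  ratio vanishes when the target coincides with the Yoruba; the default
  therefore takes the complement ($1 - r$), and `reading = "literal"`
  exposes the other reading. "Root of a population" defaults to the
  attachment node, with `node = "leaf"` available; note that an
  attachment-node reading needs enough taxa for attachment nodes to be
  distinct (on a 4-taxon tree the target and reference collapse onto the
  same internal node, which is why the worked examples place the full
  recipient set on the tree).

All three estimators recover truth within ±5 points on noise-free linear
inputs and are monotone in the true fraction (tested).

## Diversity statistics

Runs of homozygosity use the two-pass windowed scan with the standard
parameter set (50-SNP windows, at most 1 heterozygote and 5 missing per
homozygous window, SNP eligibility at a 5% overlapping-window fraction,
runs of at least 100 SNPs and 500 kb, density at least one SNP per 50 kb,
splits at gaps over 500 kb). Windows at chromosome ends are truncated, not
dropped, and eligibility uses the number of windows actually overlapping
each SNP — this is this implementation's fixed convention for an edge case
the scanning tools leave undocumented. The boundary blur this induces is a
few SNPs; planted-segment recall and precision are ≥ 0.95 for segments
≥ 1 Mb at ≤ 10 kb spacing (tested).

LD decay bins genotype-dosage $r^2$ (composite LD — the tool default being
mirrored) into the ten printed distance classes; the printed list omits
40–45 kb, which is preserved as printed with an opt-in flag to add the
missing bin. The folded SFS and LD are computed after downsampling to five
individuals, ten fresh draws without replacement (seeds derived from the
master seed by replicate index), averaged. Note that with $n$ samples the
independence floor of $r^2$ is approximately $1/(n-1)$, i.e. 0.25 at
$n = 5$ — decay curves from such small samples must be read relative to
that floor. $H_o$ divides each individual's heterozygous-site count by the
*total* SNP count of the dataset; $F_{is}$ is the method-of-moments
coefficient with the $n/(n-1)$ small-sample correction on expected
homozygosity.

## Y-STR descent clusters and the rho TMRCA

The descent cluster around a modal haplotype is delimited by breadth-first
growth over sampled haplotypes connected by single-locus, single-step
edges — an explicit operationalization chosen here because the delimitation
criteria cited in the mirrored protocol are not restated there. Chains of
sampled intermediates are included; isolated multi-step mutants are not.
Modal-haplotype ties break deterministically (larger repeat sum, then
lexicographic), so results are input-order invariant (tested).

The rho statistic is the mean single-step mutational distance of cluster
members to the ancestral haplotype; age is $\rho / (L \mu)$ generations
with $\mu = 0.0025$ per locus per generation over $L = 10$ loci (eleven
loci are typed in the mirrored data but the duplicated multi-copy locus is
excluded from distances, hence 10) and 30-year generations. The standard
error uses the star-genealogy approximation
$\sqrt{\rho / n} / (L\mu)$; empirical 95% CI coverage on simulated star
clusters falls in $[0.88, 0.99]$ (tested) — adequate, though the normal
approximation on what is a scaled Poisson mean is visibly discrete at
small $n\rho$. When $\rho = 0$ the upper limit substitutes the exact
Poisson bound for zero observed mutations.

Match-profile summaries reduce a haplotype match table to the focal
region's match share, sample-size share and their ratio; a ratio of 1
means matches proportional to sampling effort.

## The social-selection recursion

With dominant fraction $d$, success multiplier $b$, and carrier fraction
$q$ among dominants, sons of dominant fathers form
$f = bd/(bd + 1 - d)$ of the next generation and the lineage frequency
updates as $p' = (bdq + p - dq)/(bd + 1 - d)$. Status is culturally
heritable with fidelity $\tau$: $\tau d$ of the dominant class is refilled
from sons of dominant fathers, lineage sons first, the remainder at
random. With $\tau = 1$, $q_0 = 1$ the recursion has the closed form
$p_t = 1 - (1 - p_0)/(bd + 1 - d)^t$, matched by the iterator to
$10^{-12}$ over 100 generations, and the Wright–Fisher simulator tracks the
deterministic trajectory within Monte-Carlo error (both tested).

The published account of this model gives the headline scenario (dominant
men at 5%, three-fold mating success, ~500 years) but its appendix
recursion is not available; this module therefore defines its recursion
explicitly and treats the three-fold figure as a scenario to explore with
`advantage_grid()` rather than a number to reproduce. Under this module's
default ($\tau = 1$, $q_0 = 1$, $p_0 = d$), reaching the observed 0.6
lineage frequency in 16 generations needs $b^\* \approx 2.11$ (closed-form
inversion, used as a regression anchor in the tests); lower transmission
fidelity or a smaller founding frequency pushes $b^\*$ upward, and the grid
exposes which settings require a three-fold advantage. No single setting is
asserted as "the" published model.

## Problem sizes and reproducibility

The test-suite and acceptance analyses use the study's scale where the
statistic demands it (150k SNPs for kinship, Fst and projection-based
ancestry; 1000 replicate star clusters for the TMRCA) and reduced scales
where the property under test is scale-free (600–5000-site painting
panels; 10–12-individual ROH cohorts). The pipeline orchestrator derives
per-stage seeds by hashing the master seed with the stage name, so adding
or disabling a stage never reshuffles another stage's draws, and its
manifest records an MD5 checksum for every file written.

## Known limitations

* Synthetic genotypes are unlinked given the source frequencies; LD-based
  statistics are exercised on constructed fixtures rather than
  recombination-driven data.
* The painting model assumes uniform site spacing and a uniform donor
  prior; neither a genetic map nor donor-specific copying propensities are
  modelled.
* The admixture EM optimizes the same binomial likelihood as the standard
  block-relaxation tools but converges more slowly near the optimum;
  restarts (default 20) guard against local maxima. Cross-validation for
  choosing $K$ is out of scope.
* The deterministic dominance recursion models males only; female
  demography enters solely through the normalization of male reproductive
  success.
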