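Package: maroongen
Title: Population-Genomic Analysis of Admixed Creole and Maroon Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for the population genomics of
    admixed island communities founded during the Atlantic slave trade:
    variant quality control and kinship pruning, Li-Stephens haplotype
    painting with expected chunk-count coancestry matrices, total variation
    distance and Neighbor-Joining ancestry geometry, three admixture
    proportion estimators (Bernstein, PCA centroid projection, tree
    geometry), genome-wide diversity statistics (runs of homozygosity, LD
    decay, folded site frequency spectra, heterozygosity and inbreeding
    coefficients), Y-STR descent-cluster TMRCA estimation with the rho
    statistic, and a deterministic model of socially selected Y-lineage
    expansion. Every analysis is exercisable on synthetic data with known
    ground truth generated under Balding-Nichols differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
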