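Package: crossplan
Title: Genomic Mating with Parameterization-Consistent Cross Prediction and Diversity Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans crosses for plant and animal breeding programs from genome-wide
    marker data. Predicts family means and within-family variances under dominance
    for diploids and autotetraploids by composing per-locus genotype-class
    distributions for arbitrary breeding schemes (F1, selfing chains, doubled
    haploids, clonal evaluation, testcrosses) with linkage-disequilibrium
    propagation across loci; supplies the usefulness criterion; estimates the
    proportion of additive standard deviation lost (PropSD) from genomic
    relationship matrices without marker effects; and searches for constrained
    mating plans with a hybrid genetic-algorithm / simulated-annealing optimizer.
    Includes a whole-genome meiosis simulator used as a Monte-Carlo oracle and a
    synthetic-data module for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    Rcpp,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
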