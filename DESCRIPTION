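Package: cgreg
Title: Constrained Genomic Regression for Founder Genome Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates, per individual, the proportions of its genome
    inherited from a set of founder populations by regressing observed
    allele counts on expected allele contents (twice the founder allele
    frequencies) under simplex constraints, solved exactly as a convex
    quadratic programme. Includes founder allele-frequency panel
    construction from labelled reference genotypes, readers and writers
    for VCF, PLINK text and simple tab-separated formats, a
    forward-in-time admixture simulator with crossover gamete formation
    and exact ancestry-truth tracking, evaluation metrics (maximum error,
    bias, mean squared error, grand-mean-centred correlation, mean
    absolute error) with per-category breakdowns, and a trial harness for
    fully specified, under-specified and miss-specified founder designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
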