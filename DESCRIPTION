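Package: introscan
Title: Detecting Indica-Japonica Introgression in Admixed Rice Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for tracing parental-genome introgression in admixed
    inbred rice cultivars derived from indica x japonica crosses. Provides
    informative-SNP panel design via adjacent-pair linkage-disequilibrium
    (Delta-squared) subset simulation, per-population diversity statistics
    (minor allele frequency, expected heterozygosity, polymorphism
    information content) with resampling-based sample-size adjustment,
    an adjusted allele-frequency ancestry scan with five-SNP window
    quantile bands and skewed-region calls, genome-type classification of
    cultivars, a mixed-linear-model association scan with family-wise
    permutation P-values, candidate-feature interval lookup, and a
    breeding-population simulator that generates mosaic admixed genotypes,
    QTL-driven phenotypes and the ground truth needed for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
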