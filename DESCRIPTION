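Package: lupings
Title: Genomic Selection and Managed-Environment Validation for White Lupin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end genomic selection toolkit for white lupin (Lupinus albus)
    breeding: quality control and deterministic imputation of GBS SNP dosage
    matrices, rrBLUP / GBLUP / weighted GBLUP prediction of breeding values with
    REML-estimated shrinkage, cross-validated predictive ability, phenology-
    constrained selection of contrasting (top/mid/bottom) genotypes for adaptation
    to drought and moderately calcareous soil, and analysis of 2 water x 2 soil
    managed-environment factorial trials (partitioned ANOVA with block-within-
    environment error terms, LSD mean separation, crossover genotype-by-environment
    detection, water-budget accounting). Includes a seeded simulator of
    factorial-cross line populations, landrace collections, additive trait
    architectures and randomized-complete-block trials, so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
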