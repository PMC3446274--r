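Package: evorisk
Title: Differential Variability Analysis and Outlier-Based Risk
    Prediction for DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially variable CpGs (DVCs) in normalized
    Illumina-style beta-value methylation matrices using an age-adjusted
    Bartlett test, identifies age-hypermethylated CpGs by supervised
    linear regression, and trains an EVORA-style adaptive-index risk
    classifier: candidate risk CpGs are the overlap of hypervariable DVCs
    and age-hypermethylated CpGs, outlier samples are defined in a
    COPA-transformed (median/MAD) basis, and a ten-fold internal
    cross-validation selects the outlier threshold and risk-CpG set.
    Per-sample risk is the fraction of risk CpGs exceeding the threshold,
    on the COPA or beta scale. Includes Storey q-value FDR estimation,
    Fisher/relative-odds-ratio/binomial gene-set enrichment, ROC/AUC
    evaluation with repeated train/test partitions, and a fully seeded
    synthetic-cohort generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
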