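Package: uroevmir
Title: Urinary Extracellular-Vesicle miRNA Classification of Pancreatic Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discriminating pancreatic ductal
    adenocarcinoma (PDAC) from high-risk individuals using urinary
    extracellular-vesicle small-RNA sequencing. Covers UMI-deduplicated
    miRNA read quantification, count filtering and counts-per-million
    normalization, negative-binomial Wald differential expression with
    Benjamini-Hochberg adjustment and Spearman stage-trend testing,
    bootstrap feature selection with a gradient-boosted classifier
    calibrated to a target sensitivity, and a diagnostic evaluation layer
    (ROC/AUC, binomial confidence intervals, stage-stratified sensitivity,
    predictive values, CA19-9 comparison, subgroup-bias tests). Includes a
    negative-binomial cohort simulator with planted stage-dependent effects
    and an analytic likelihood-ratio oracle for benchmarking.
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
    utils,
    xgboost
Suggests:
    Biostrings,
    DESeq2,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
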