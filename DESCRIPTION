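Package: oncofetal
Title: Oncofetal Signature Discovery, Scoring and Survival Analysis for
    Liver Cancer Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects a fetal/tumor epithelial co-expression module from
    single-cell RNA-seq pseudobulks, derives an oncofetal gene signature,
    scores cells and bulk samples with a control-binned module score,
    classifies fetal-like cells with a normal-percentile zeroing rule,
    calls malignant cells from reference-centred window-smoothed copy-number
    profiles, prioritises candidate regulators by joint signature
    association and CRISPR proliferative dependency, and relates oncofetal
    scores to clinical covariates and survival through a maximally selected
    log-rank cutpoint with a permutation p-value. A synthetic-data module
    generates every input with known ground truth so each stage is testable
    without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
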