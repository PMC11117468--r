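Package: lcquotient
Title: Urine Light Chain/eGFR Quotient for Ruling Out Myeloma Cast
    Nephropathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the non-invasive urine involved light chain to
    estimated glomerular filtration rate (LCurine/eGFR) quotient rule for
    predicting myeloma-associated cast nephropathy, together with the
    machinery needed to validate it: CKD-EPI creatinine eGFR (2009 and
    2021 equations, forward and inverse), light-chain-type-specific
    classification, four-field-table diagnostic accuracy with exact
    binomial confidence intervals, rank-based ROC/AUC, Kruskal-Wallis and
    Dunn post hoc comparisons with Benjamini-Hochberg adjustment, and a
    log-normal virtual-cohort generator calibrated to the per-histology
    summary statistics of the original two-center validation cohort so
    that every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
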