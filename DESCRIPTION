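Package: momscreen
Title: Multiple-of-the-Median Normalization and Risk Models for Maternal
    Plasma Cell-Free RNA Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for second-trimester prenatal screening
    with maternal plasma cell-free RNA markers (PSME2, NAMPT, APOA1, APOA4,
    Hsa-Let-7g), cervical length and mean arterial pressure. Converts qPCR
    threshold cycles to relative expression (delta-delta CT), normalizes
    marker levels to multiples of the median (MoM) against covariate-regressed
    medians fit on unaffected pregnancies, runs case/non-case association
    screens (Wilcoxon rank-sum, chi-square, correlation), fits logistic risk
    models over log10 MoMs and clinical covariates with missingness-pattern
    sub-models, ships published risk equations for spontaneous preterm
    birth and preeclampsia as fixtures, and summarizes screening performance
    as Mann-Whitney AUC with DeLong confidence intervals and detection rates
    at fixed false-positive rates from control-score percentiles. Includes a
    synthetic cohort generator emulating the statistical structure of a
    high-risk obstetric cohort so the full pipeline is testable without
    access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
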