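Package: cortasym
Title: Cortical Asymmetry Index and Inference Pipeline for Autosomal
    Dominant Alzheimer's Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the cortical asymmetry index (CAI), a scalar
    per-scan measure of left-right cortical thickness asymmetry defined
    as the Jensen-Shannon distance between the two hemispheres'
    thickness probability distributions over the 34 Desikan-Killiany
    regions, and implements the full cross-sectional, correlational and
    longitudinal inference pipeline used to study CAI in autosomal
    dominant Alzheimer's disease: covariate-adjusted Freedman-Lane
    permutation tests, ANCOVA with pairwise Benjamini-Hochberg-corrected
    contrasts, ROC biomarker comparison, Spearman/Pearson association
    batteries against NfL, MMSE and estimated years to onset, and
    penalized-spline trajectory models of CAI against estimated years to
    onset. A synthetic cohort generator with the covariate structure of
    ADAD observational cohorts makes every stage testable without
    participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    jsonlite,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
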