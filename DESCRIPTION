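Package: cfratio
Title: CD8+ T Cell to Cancer-Associated Fibroblast Ratio Analysis for
    Tumor Microenvironment Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Signature-based scoring of tumor-microenvironment cell
    populations from bulk expression data and stratification of patients
    by the CD8+ T cell to cancer-associated fibroblast ratio (CFR).
    Implements single-sample gene set enrichment (ssGSEA) scoring with a
    shipped immune-cell and fibroblast signature registry, the CFR and
    immune-cell/CAF-ratio statistics in both score-difference and
    immunohistochemistry area-ratio forms, survival-optimal
    dichotomization by maximally selected rank statistics, Kaplan-Meier /
    log-rank / Cox survival comparison, a response-association battery
    (objective response rates, contingency tests, logistic biomarker
    combination, nonparametric ROC AUC, per-gene mutation enrichment),
    and a synthetic cohort generator emulating the latent statistical
    structure that the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
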