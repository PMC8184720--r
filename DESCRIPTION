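Package: grpscore
Title: Glycolysis-Related Prognostic Scoring from Multi-Cohort Survival
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates a glycolysis-related prognostic (GRP)
    gene-expression score for survival cohorts. Each candidate gene is
    screened per cohort by median-dichotomized Cox proportional-hazards
    regression, per-cohort hazard ratios are pooled by fixed-effects
    inverse-variance meta-analysis, and significant genes are combined
    into a weighted expression score with weights (HR - 1)/SE(HR). The
    package also provides Kaplan-Meier and log-rank evaluation,
    time-dependent ROC for survival with inverse-probability-of-censoring
    weights, single-sample gene-set enrichment (ssGSEA) for
    immune-infiltration scoring, chemotherapy-response discrimination
    (ROC/AUC, ridge-logistic predictor combination), and a synthetic
    multi-cohort generator with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    metafor
Config/testthat/edition: 3
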