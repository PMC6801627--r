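Package: uropanel
Title: Urinary Biomarker Panel Discovery for Ovarian Cancer Triage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovery and validation machinery for multimarker diagnostic
    panels from urinary protein concentrations, built around the
    benign-versus-malignant pelvic mass problem. Provides cohort readers and
    accounting, empirical AUC with DeLong variance, covariance and paired
    tests, stratified subsample/bootstrap AUC summaries, per-marker
    differential screening with multiplicity correction, L1-regularized
    logistic marker ranking over repeated cross-validation, nested
    cross-validated panel selection over 2-4 marker combinations with
    F-score decision thresholds, evaluation by disease stage and with a
    menopausal-status covariate, and a calibrated binormal synthetic-cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
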