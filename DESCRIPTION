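Package: omipipe
Title: Occlusion Myocardial Infarction Prediction from ECG and Early Emergency Department Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying occlusion myocardial
    infarction (OMI) detection among emergency-department chest-pain
    patients. Generates synthetic cohorts (12-lead ECG waveforms with
    controllable ST-segment deviation, tabular history, point-of-care labs,
    troponins, and registry outcomes), annotates OMI with a rule-based
    decision tree over registry data, applies guideline ST-elevation
    (STEMI) criteria to median beats as a rule-based comparator, trains a
    residual convolutional ECG encoder fused with tabular feature groups
    into a regularized logistic risk model, and evaluates it against the
    STEMI rule at matched specificity with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
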