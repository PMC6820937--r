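Package: glycogfr
Title: Glycemia-Aware Approximation of Measured GFR in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating and approximating glomerular filtration
    rate (GFR) in adults with type 2 diabetes. Implements the CKD-EPI and
    MDRD creatinine equations, Du Bois body-surface-area indexing, and a
    family of stratified glycemia-aware approximating equations that add
    fasting plasma glucose and HbA1c to age, sex and serum creatinine.
    Provides the full derivation pipeline (linear models with first-order
    autoregressive within-subject correlation, exhaustive AIC model
    selection, sex-by-creatinine-quartile stratification, subject-level
    10-fold cross-validation), evaluation metrics (P30, bias, RMSE,
    dependent-correlation tests, ROC/AUC with the DeLong test), and a
    calibrated synthetic longitudinal diabetic cohort generator for testing
    the pipeline without access to private clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    pROC,
    jsonlite
Config/testthat/edition: 3
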