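Package: mrdash
Title: Silent Atrial Fibrillation Risk Scoring in Elderly Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deriving and validating integer clinical risk scores
    for silent atrial fibrillation (AF) from long-term ECG screening cohorts
    of adults aged 65 years and over. Provides a synthetic-cohort generator
    calibrated to published covariate prevalences and odds ratios,
    guideline-based phenotyping (CKD-EPI 2009 eGFR, hypertension, diabetes,
    chronic kidney disease, the greater-than-30-second AF episode rule),
    univariate and multivariable logistic association analysis with
    poststratification weights, the MR-DASH score derivation procedure
    (repeated 2/3-1/3 split resampling with rounded-odds-ratio point
    assignment), and ROC validation with DeLong confidence intervals and
    minimal-distance-to-(0,1) cutoff selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
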