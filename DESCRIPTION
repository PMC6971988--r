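Package: ehrprev
Title: Selection-Bias Evaluation for Child Weight-Status Prevalence from
    Incomplete Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess selection bias when childhood weight-status
    prevalence is estimated from incomplete height and weight measurements in
    electronic health records. Provides LMS growth-standard BMI z-scores and
    weight-status classification, a logistic model of measurement missingness
    with adjusted odds ratios, stabilized inverse-probability weights with
    linearized-variance weighted prevalence, multiple imputation of weight
    status with Rubin's-rules pooling, direct age standardization, and a
    synthetic cohort generator calibrated to a published regional pediatric
    cohort so that complete-case, IPW and MI estimators can be compared under
    known missingness mechanisms.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
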