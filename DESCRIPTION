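Package: absst
Title: Short-Form Screening Tool Validation with Partial Credit Rasch
    Models and Pivot-Anchored Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Psychometric validation pipeline for deriving a short-form
    patient-reported bladder symptom screening instrument and its referral
    scoring algorithm.  Implements classical test theory item screening
    (floor/ceiling effects, corrected item-total correlations, KR-20),
    Partial Credit Model estimation by joint maximum likelihood with
    infit/outfit mean-square fit statistics and separation/reliability
    indices, pivot-anchored clinician threshold scoring, rule-based
    short-form item reduction, and screening cut-point diagnostics
    (odds ratios, sensitivity/specificity, predictive values, ROC
    c-statistics, logistic regression, Hosmer-Lemeshow calibration).
    Includes a synthetic-data module emulating the multi-centre multiple
    sclerosis study design that motivated the instrument, plus a
    deterministic score/label fixture for the published cut-point table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
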