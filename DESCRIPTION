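Package: dmscore
Title: Point-Based Diabetes Case Finding from Electronic Health Record Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a real-time, point-based case-finding algorithm for
    diabetes mellitus operating on longitudinal electronic health record (EHR)
    event streams (encounter ICD-9 diagnoses, laboratory results, medication
    orders, and problem-list / past-medical-history entries). Each qualifying
    event contributes a fractional point value; patients are classified as
    'no diabetes', 'possible diabetes', or 'diabetes' according to whether
    their cumulative total is zero, strictly between zero and one, or at least
    one point, and the earliest diagnosis date is the first calendar date on
    which the accumulated total reaches the threshold. Also provides a
    two-ICD-9-code claims-based comparator, validation statistics against
    gold-standard labels (sensitivity, specificity, predictive values, Cohen's
    kappa with linear weights, ROC threshold sweeps, and diagnosis-date
    agreement within a configurable window), and a seeded synthetic-cohort
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    caret,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
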