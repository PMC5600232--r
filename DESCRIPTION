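Package: cqival
Title: Two-Level Validation Toolkit for the CQI Inpatient Hospital Care Questionnaire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating patient-experience questionnaires of the
    Consumer Quality Index (CQI) family at both the department and hospital
    level. Provides a hierarchical ordinal survey simulator with known
    variance components and factor structure, exclusion filtering and
    response-rate accounting, chained-equations multiple imputation with
    predictive mean matching and Rubin's-rules pooling, subscale scoring
    with Cronbach's alpha and inter-scale overlap screens, confirmatory
    factor analysis for ordinal items via polychoric correlations and
    diagonally weighted least squares with CFI/TLI/RMSEA acceptance logic,
    construct-validity regression on global ratings, and unbalanced nested
    generalizability (G-study/D-study) analysis with minimum-sample solvers
    based on the standard error of measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    yaml
Config/testthat/edition: 3
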