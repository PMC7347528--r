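Package: scoreupdate
Title: Validation and Updating of Points-Based Clinical Risk Scorecards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating and updating points-based clinical risk
    scorecards such as antenatal risk-selection instruments. Implements
    cumulative-score arithmetic and high-risk classification, temporal
    development/validation splits, multiple imputation by chained equations
    for binary predictor items with Rubin pooling, discrimination and
    calibration assessment (AUC with DeLong or bootstrap confidence
    intervals, recalibration intercept and slope, threshold metrics,
    descriptive group comparisons), and a four-step model-updating
    procedure: candidate screening on top of the cumulative score,
    backward elimination, heuristic shrinkage, coefficient-sign
    evaluation, and rescaling of regression coefficients into additional
    integer score points. A synthetic-cohort generator reproduces the
    statistical structure of a multicentre antenatal cohort so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ggplot2,
    optparse
Config/testthat/edition: 3
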