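Package: paeecal
Title: Calibration and Validation of Accelerometer and Heart-Rate Energy
    Expenditure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive and validate population-specific prediction
    equations for physical activity energy expenditure (PAEE) from
    accelerometer counts and heart rate, against an indirect-calorimetry
    criterion.  Implements the Weir equation for energy expenditure from
    respiratory gas exchange, the physiological cost index, RMR-referenced
    METs, ordinary least-squares calibration with leave-one-participant-out
    cross-validation, Bland-Altman limits of agreement, standard error of
    the estimate and per-activity error statistics, plus a synthetic-cohort
    generator that emulates a treadmill protocol in unilateral amputee,
    bilateral amputee, and non-injured control groups so the whole pipeline
    runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
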