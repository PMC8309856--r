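Package: respirad
Title: Respiration Rate from IR-UWB Radar and Drowsiness Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts respiration rate (breaths per minute) from impulse-radio
    ultra-wideband (IR-UWB) radar baseband frame matrices via effective-range
    bin selection, per-frame trapezoidal area-under-curve, zero-phase
    tenth-order Butterworth low-pass filtering and peak counting, and
    classifies drowsy versus non-drowsy driver state from respiration rate and
    age with a suite of standard machine-learning models plus a fixed
    respiration-rate threshold rule. Includes a parametric chest-motion radar
    simulator and a paired-driver cohort generator so the whole pipeline is
    testable with known ground truth and no hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    pracma,
    signal,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
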