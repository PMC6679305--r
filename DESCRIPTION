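Package: codwork
Title: Turn Energetics and Kinematics from a Pelvis-Worn Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the direction, approach/exit speed and positive/negative
    external mechanical work of 180-degree changes of direction during shuttle
    running from a single pelvis-worn inertial measurement unit (tri-axial
    accelerometer, gyroscope and barometer). Reference values are derived from
    centre-of-mass trajectories recorded by optical motion capture; the two
    measurement systems are aligned by cross-correlation of their detected turn
    events. Eighteen inertial features per turn feed linear and nonlinear
    regression and classification models evaluated under cross-validation. A
    synthetic shuttle-run generator with closed-form ground truth makes every
    stage of the pipeline testable without laboratory recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    signal,
    pracma,
    withr,
    MASS,
    e1071,
    nnet,
    xgboost,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
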