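Package: insolegait
Title: Gait Event Detection and Sarcopenia Screening from Foot-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based detection of the seven gait-cycle events (heel strike,
    opposite toe-off, heel rise, opposite heel strike, toe-off, feet adjacent,
    tibia vertical) from bilateral foot-mounted accelerometer and gyroscope
    recordings, spatiotemporal and per-phase descriptive-statistic gait features,
    zero-velocity-update stride-length estimation, Shapley-value feature selection
    on gradient-boosted trees, and subject-wise leave-one-subject-out
    classification of sarcopenia versus normal gait. Includes a synthetic
    bilateral gait-signal generator with ground-truth event annotations for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
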