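Package: steerwake
Title: Driver Drowsiness Detection from Steering Signals with Neuro-Fuzzy
    Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects driver drowsiness from steering-wheel angle and velocity
    recordings labelled with the Karolinska Sleepiness Scale (KSS). Signals
    are segmented into overlapping windows, detrended against road curvature,
    and summarised by 36 time- and frequency-domain features per window. Four
    filter statistics (Fisher score, point-biserial correlation, Welch t
    statistic, mutual information) are fused per feature by a zero-order
    Takagi-Sugeno fuzzy system into an importance degree; membership-function
    and consequent parameters are trained by particle swarm optimization
    against the validation error of a support-vector-machine wrapper.
    Includes a synthetic steering-behaviour generator with planted
    awake/drowsy structure so that the full pipeline is testable without
    simulator data, plus single-index baseline selectors and ROC/AUC
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
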