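Package: pmcast
Title: Hybrid Spatio-Temporal Forecasting for Urban PM2.5 Sensor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fine-grained hourly PM2.5 prediction over dense urban
    sensor networks that mix reference-grade monitors with intermittently
    available low-cost sensors. Combines a linear-Gaussian spatio-temporal
    hierarchical state-space model (fit by EM with Kalman smoothing) for gap
    filling, per-sensor piecewise-cubic diurnal baselines fit per 8-hour slot,
    and a message-passing recurrent neural network over the complete sensor
    graph that learns short-term residual dynamics from neighboring monitors
    and their pairwise distances. Includes a seeded synthetic-city simulator,
    k-nearest-neighbor recurrent and persistence baselines, masked evaluation
    metrics (MAPE, RMSE), hazard-exceedance detection, and declarative
    pipeline composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
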