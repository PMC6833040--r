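Package: cgmcast
Title: Short-Term Blood Glucose Forecasting from Continuous Glucose Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how much continuous glucose monitoring (CGM)
    history is needed for accurate short-term blood glucose forecasting.
    Provides a synthetic flash-glucose-monitor cohort generator with a
    calibrated sensor error model (interstitial lag, multiplicative noise,
    range clipping), FIFO sliding-window and time-delay embedding utilities,
    three per-patient univariate forecasters (ARIMA with automatic order
    selection, random forest, support vector regression) plus a persistence
    baseline, and a rolling-origin evaluation harness that maps root mean
    square error over grids of past-window length, sampling frequency and
    prediction horizon, with cross-patient aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
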