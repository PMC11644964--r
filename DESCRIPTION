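Package: glucast
Title: Blood Glucose Forecasting with Hybrid Convolutional-Recurrent Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-step-ahead forecasting of continuous glucose
    monitoring (CGM) time series. Provides a synthetic CGM generator with
    circadian drift, meal excursions and autocorrelated sensor noise; CSV
    input/output for two-column glucose traces; series-to-supervised
    windowing with chronological train/test splitting and leakage-free
    min-max scaling; five forecasting architectures (LSTM, GRU, CNN,
    CNN-LSTM, CNN-GRU) with training by backpropagation and Adam;
    Bayesian hyperparameter optimization with a Gaussian-process surrogate
    and expected-improvement acquisition; RMSE/MAE evaluation over a grid
    of lag/horizon scenarios; and a streaming inference engine with an
    in-process publish/subscribe broker, sliding-window forecasting and a
    JSONL sink. A command-line interface exposes each pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
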