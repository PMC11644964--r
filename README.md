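# glucast

Multi-step-ahead forecasting of continuous glucose monitoring (CGM) time
series in R, built around hybrid convolutional-recurrent models.

People with type 1 diabetes wear CGM sensors that report blood glucose
(mmol/L) every ~15 minutes. Forecasting the level minutes to an hour ahead
from the univariate history alone gives patients and clinical systems time
to react. `glucast` provides the complete pipeline for this task:

* **Synthetic CGM generation** — baseline + circadian sinusoid + log-normal
  meal excursions with exponential decay + AR(1) sensor noise, clamped to
  2–25 mmol/L, so everything is testable without patient data
  (`simulate_cgm()`, `inject_gaps()`).
* **I/O** — the two-column `Time,BGL` CSV dialect with unpadded
  month/day/year timestamps (`read_cgm_csv()`, `write_cgm_csv()`), plus a
  bundled 12-reading sample trace (`cgm_sample()`).
* **Series-to-supervised windowing** — `X[i,] = g[i..i+lag-1]`,
  `y[i] = g[i+lag+horizon-1]` (direct multi-step strategy), chronological
  75/25 splitting, and leakage-free min-max scaling fitted on training
  data only.
* **Five architectures** — GRU, LSTM, CNN, CNN-LSTM and CNN-GRU
  (`Conv1D → max-pool → recurrent → flatten → dense → output` for the
  hybrids), with forward/backward passes, BPTT and the Adam optimizer
  implemented in the package and verified against finite differences.
* **Bayesian hyperparameter optimization** — Gaussian-process surrogate
  with expected-improvement acquisition over the mixed search space
  (units 50–500, dropout 0.1–0.9, L2 ∈ {0.01, 0.05, 0.005, 0.001},
  filters ∈ {200, 128, 250}, kernel ∈ {3, 4}), plus a random-search
  baseline (`bayes_optimize()`, `select_architecture()`).
* **Evaluation** — RMSE = √(Σ(yᵒᵇˢ−yᵖʳᵉᵈ)²/n) and MAE = Σ|yᵒᵇˢ−yᵖʳᵉᵈ|/n in
  original units over a six-scenario lag/horizon grid, with a persistence
  (last-value) baseline (`run_scenario()`).
* **Streaming inference** — an in-process publish/subscribe broker, sensor
  replay/simulation, sliding-window online forecasting that exactly
  reproduces batch predictions, and a JSONL sink (`stream_forecast()`).

Results are tibbles throughout, with `autoplot()`, `tidy()` and `glance()`
methods, and a CLI (`inst/cli/glucast`, or `glucast_cli()`) exposing
`generate | train | tune | evaluate | stream`.

## Worked example

```r
library(glucast)

series <- simulate_cgm(cgm_sim_params(n_points = 600, seed = 1))
series
#> <cgm_ts: 600 readings, 2020-11-03 00:00 to 2020-11-09 05:45, 5.6-14.5 mmol/L>

ds <- to_supervised(series, lag = 10, horizon = 5)
ds
#> <supervised_ds: 586 samples, lag 10, horizon 5, original units>

parts <- chronological_split(ds, 0.75)
scaler <- fit_scaler(parts$train)

hp <- hyper_params("cnn_gru", units = c(32, 16), lag = 10,
                   filters = 32, kernel = 3)
fit <- fit_forecaster(build_model(hp), apply_scaler(parts$train, scaler),
                      epochs = 20, batch_size = 1, seed = 1)
fit
#> <trained_forecaster: cnn_gru, lag 10, 8449 weights, 20 epoch(s), final loss 0.02667>

pred <- predict(fit, apply_scaler(parts$test, scaler)$X)  # mmol/L
eval_metrics(parts$test$y, pred)
#> # A tibble: 1 × 3
#>    rmse   mae     n
#>   <dbl> <dbl> <int>
#> 1  1.40  1.03   147

eval_metrics(parts$test$y, persistence_forecast(parts$test$X))
#> # A tibble: 1 × 3
#>    rmse   mae     n
#>   <dbl> <dbl> <int>
#> 1  1.68  1.18   147
```

The hybrid forecasts the held-out quarter of the trace five steps
(~75 minutes) ahead with RMSE 1.40 mmol/L, beating the naive
last-value-carried-forward baseline (1.68 mmol/L). `run_scenario()` repeats
this comparison across the whole lag/horizon grid and all model kinds;
`autoplot()` on its report draws the per-scenario RMSE/MAE bars.

For the scientific background — model equations, preprocessing protocol,
search-space design, what the synthetic generator does and does not
emulate — see the vignette source in
`vignettes/glucose-forecasting.Rmd`.

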