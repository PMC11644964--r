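---
title: "Multi-step blood glucose forecasting with hybrid convolutional-recurrent models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-step blood glucose forecasting with hybrid convolutional-recurrent models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucast)
```

## The problem

People with type 1 diabetes rely on continuous glucose monitoring (CGM)
sensors that report blood glucose every few minutes. Forecasting the glucose
level several steps ahead from the recent history alone — no insulin or meal
covariates — gives patients and closed-loop systems time to react to
excursions. `glucast` implements this as a direct multi-step forecasting
problem on a univariate series in mmol/L: a window of `lag` consecutive
readings is mapped to the reading `horizon` steps beyond the window's end,
and a separate model is trained for every (lag, horizon) pair rather than
iterating one-step forecasts (the direct strategy; errors do not compound
across the horizon, at the price of one model per scenario).

## The model family

Five architectures are built from the same layer set:

* **GRU / LSTM** — a single recurrent layer reading the window one value at
  a time, followed by a linear output unit. GRU cells gate their hidden
  state with sigmoid update and reset gates
  \(z_t = \sigma(W_z x_t + U_z h_{t-1} + b_z)\),
  \(r_t = \sigma(W_r x_t + U_r h_{t-1} + b_r)\), and update
  \(h_t = z_t h_{t-1} + (1-z_t)\,\phi(W_h x_t + U_h (r_t \odot h_{t-1}) + b_h)\);
  LSTM cells use forget/input/output gates around an additive cell state.
* **CNN** — a 1-D convolution (ReLU, valid padding) extracts local shape
  features, max-pooling (width 2) halves the feature map, and a
  fully-connected ReLU layer feeds the output unit.
* **CNN-GRU / CNN-LSTM** — the hybrids: convolution and pooling first, the
  recurrent layer then reads the pooled feature sequence, and its full
  hidden-state sequence is flattened into a dense ReLU layer before the
  output unit. The convolution supplies local pattern detectors; the
  recurrent layer models how those patterns evolve.

The candidate/output activation of the recurrent cells is ReLU by default
(`activation = "tanh"` is available); gates are always sigmoid. Dropout sits
after the recurrent layer (after the hidden dense layer for the plain CNN)
and L2 weight decay applies to recurrent and dense kernels.

All layer arithmetic — forward passes, backpropagation through time, and the
Adam optimizer — is implemented in the package itself and is verified in the
test suite against central finite differences for every architecture
(relative error below 1e-5 on sampled weights). Training uses
mean-squared-error loss, batch size 1 and 20 epochs by default, Adam at step
size 0.001, Glorot-uniform initialisation (unit forget-gate bias for LSTM),
and an epoch-shuffled sample order drawn from the seeded RNG, so a seed
fully determines the fitted weights.

## Preprocessing and evaluation protocol

* **Windowing.** `to_supervised()` yields `N - lag - horizon + 1` samples;
  each predictor row is a contiguous window and the target is the value
  `horizon` steps past its end. Lags and horizons are counts of samples:
  the minute labels of the default `scenario_grid()` — lags 3, 10, 13, 18,
  20, 30 paired with horizons 5, 15, 20, 25, 30, 60 — are reporting names,
  since at ~15-minute CGM sampling a literal "3 minutes of history" would
  not contain a single reading.
* **Split.** `chronological_split()` takes the first
  `floor(0.75 n)` samples for training, the rest for testing, never
  shuffling. `floor` keeps the train count deterministic and conservative.
* **Scaling.** Min-max scaling to [0, 1] is fitted on the training block
  only (predictors and targets pooled) and applied unchanged to the test
  block; out-of-range test values are deliberately not clipped. Fitting on
  the training data alone is what keeps preprocessing leakage-free, and the
  test suite asserts that perturbing test-region values cannot move the
  scaler.
* **Metrics.** RMSE and MAE, computed after inverse scaling so they are in
  mmol/L. `run_scenario()` also reports a persistence baseline (forecast =
  last value in the window): any learned model worth deploying must beat
  it, and on autocorrelated glucose data persistence is surprisingly hard
  to beat at short horizons.

## Hyperparameter search

`bayes_optimize()` implements sequential model-based search: after a few
uniform random trials, a Gaussian-process surrogate with an RBF kernel is
refitted to all successful trials and the next configuration maximises
expected improvement over a random candidate pool (256 candidates by
default), skipping configurations already evaluated, which makes the
procedure reduce to exhaustive search when the budget covers a small
discrete space. Design choices worth recording:

* Mixed-space encoding: width dimensions and dropout are rescaled to
  [0, 1]; the categorical L2 coefficient, filter count and kernel width are
  one-hot encoded. This is the standard treatment for mixed
  continuous/categorical spaces under an RBF kernel.
* The GP lengthscale is set by the median heuristic on pairwise distances
  and the targets are standardised; a small nugget (1e-4) absorbs
  objective noise. Fitting hyperparameters of the surrogate itself is
  deliberately avoided at these tiny trial counts.
* Failed trials (errors, non-finite objectives) are recorded and excluded
  from the surrogate rather than imputed.
* Default budget is 20 trials with 5 random warm-up trials.
* The default search space is units 50–500 in steps of 10 for every width
  dimension, dropout uniform in [0.1, 0.9], L2 from
  {0.01, 0.05, 0.005, 0.001}, filters from {200, 128, 250} and kernel from
  {3, 4} (kernels wider than the lag are excluded up front).

`select_architecture()` turns this into model selection: the objective is
the validation RMSE (original units) of a model trained with the sampled
configuration, where validation is the chronologically last 25% of the
training samples and the scaler is refitted on the remaining sub-training
block for every trial — the test partition is never touched during tuning.

## The synthetic CGM generator

`simulate_cgm()` exists so that every pipeline stage is testable without
any external dataset. It emulates a single patient's CGM trace as

\[ g(t) = \mathrm{clamp}\big(b + A\sin(2\pi(m(t)-360)/1440) +
  \textstyle\sum_k a_k e^{-(t-t_k)/\tau} + e_t,\ 2,\ 25\big) \]

with baseline \(b = 7\) mmol/L, a circadian sinusoid (amplitude 0.8 mmol/L,
peak at 15:00, nadir at 03:00), three daily meal excursions that rise
instantaneously and decay exponentially (\(\tau = 90\) min) with log-normal
sizes (mean 4, sd 1.5 mmol/L), and stationary AR(1) Gaussian sensor noise
(innovation sd 0.3 mmol/L, autocorrelation 0.7). Defaults were chosen once
as plausible for a 15-minute sensor on a type-1 patient: glucose mostly
5–12 mmol/L with post-meal peaks, clamped to the physiological 2–25 mmol/L
range. AR(1) is the simplest autocorrelated noise model, matching the
empirical observation that consecutive CGM errors are correlated;
two-parameter exponential meal bumps give visually CGM-like excursions
without a physiological insulin–glucose model, which is out of scope.

What the generator does **not** emulate: sensor dropout and compression
artefacts, calibration jumps, exercise- and insulin-driven dynamics, and
day-to-day behavioural variation. `inject_gaps()` adds missing spans, and
`to_supervised(max_gap_minutes =)` optionally drops windows spanning a
gap, but passing tests on synthetic data shows pipeline correctness, not
clinical performance; absolute error levels on real CGM exports will
differ.

## Numerical and degenerate-input choices

* Max-pooling uses valid width-2 pooling but passes a length-1 feature map
  through unchanged, so the shortest scenario (lag 3, kernel 3) remains
  usable.
* Ties in max-pooling resolve to the earlier time step.
* Constant training data make min-max scaling undefined; this is an error,
  not a silent fallback.
* Duplicate CSV timestamps are an error (silent averaging would hide
  sensor faults); out-of-order rows are sorted with a counted warning.
* Training aborts with the epoch number as soon as the epoch loss is
  non-finite.
* Streaming forecasts are clamped at 0 mmol/L on output only; model inputs
  are never clipped.
* Scaled test inputs may leave [0, 1]; that is correct behaviour under a
  train-only scaler, not an anomaly.

## The streaming pipeline

The online path mirrors the offline one: `sensor_source()` replays a trace
(or generates one live), events travel through a publish/subscribe broker,
and `stream_forecast()` maintains a sliding buffer of the model's `lag`
most recent scaled values, emitting one forecast per event from the
`lag`-th accepted event onward. The in-process broker guarantees loss-free
per-topic FIFO fan-out; an external broker adapter only has to honour the
same `publish`/`subscribe`/`poll` contract and state its delivery
guarantee. Event screening: duplicate sequence numbers are dropped,
late events beyond a configurable tolerance (default 0) are dropped with a
counter, and nonpositive readings are quarantined to a rejects table. The
central invariant, asserted in the tests, is batch/stream equivalence:
streamed forecasts equal batch predictions on the corresponding windows to
1e-9, with exactly `lag - 1` warm-up events and full accounting
(events in = forecasts + warm-up + screened).

## Problem sizes used in the shipped checks

The test suite and the reproduction script favour compact configurations —
series of 400–1000 points, widths of 8–32 units, 16–32 filters — chosen so
that each fitted model trains in seconds to tens of seconds while still
exhibiting the qualitative behaviour of interest (the hybrids beating
persistence on autocorrelated data, near-zero error on a noiseless sine).
Full-scale widths (hundreds of units, 128–250 filters) are supported and
accepted by the same code paths; they simply train proportionally longer
under batch-size-1 SGD.

## Known limitations

* Univariate only: no insulin, carbohydrate or activity covariates.
* One recurrent layer per model; stacked recurrent variants are not
  implemented.
* Training is single-threaded R; it is intended for the moderate window
  lengths and widths of this problem, not for large-scale deep learning.
* The Bayesian optimizer's surrogate uses a fixed lengthscale heuristic;
  with budgets in the hundreds a tuned GP would be preferable.
* No probabilistic forecasts; point predictions only.

## A worked run

```{r example, eval = FALSE}
series <- simulate_cgm(cgm_sim_params(600, seed = 1))
report <- run_scenario(
  series, model_kinds = c("gru", "cnn_gru"),
  hp = list(cnn_gru = function(lag)
    hyper_params("cnn_gru", units = c(32, 16), lag = lag,
                 filters = 32, kernel = 3)),
  seed = 1)
autoplot(report)
```

`scripts/acceptance.R` runs exactly this experiment plus the sine learning
check and writes the resulting RMSE/MAE values to JSON; see the README for
how to invoke it.
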