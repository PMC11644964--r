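# Shared fixtures and independent oracles, all built in code.

# deterministic positive sine trace as a CGM series
sine_series <- function(n = 500, period = 40, level = 7, amplitude = 2) {
  cgm_series(as.POSIXct("2020-11-03", tz = "UTC") + 900 * (0:(n - 1)),
             level + amplitude * sin(2 * pi * (0:(n - 1)) / period))
}

# mean-reverting AR(1) trace (no meals, no circadian term)
ar_series <- function(n = 400, seed = 7, phi = 0.8, noise_sd = 0.5) {
  simulate_cgm(cgm_sim_params(n, circadian_amplitude = 0,
                              meal_times = character(0),
                              noise_sd = noise_sd, ar_coefficient = phi,
                              seed = seed))
}

# small configurations that train in seconds
tiny_hp <- function(kind, lag = 10) {
  switch(kind,
         gru = hyper_params("gru", units = 8, lag = lag, dropout = 0.1),
         lstm = hyper_params("lstm", units = 8, lag = lag, dropout = 0.1),
         cnn = hyper_params("cnn", units = 8, lag = lag, dropout = 0.1,
                            filters = 6, kernel = min(3, lag)),
         cnn_gru = hyper_params("cnn_gru", units = c(8, 6), lag = lag,
                                dropout = 0.1, filters = 6,
                                kernel = min(3, lag)),
         cnn_lstm = hyper_params("cnn_lstm", units = c(8, 6), lag = lag,
                                 dropout = 0.1, filters = 6,
                                 kernel = min(3, lag)))
}

# independent brute-force series-to-supervised enumeration
oracle_supervised <- function(values, lag, horizon) {
  n <- length(values) - lag - horizon + 1
  X <- matrix(NA_real_, n, lag)
  y <- numeric(n)
  for (i in seq_len(n)) {
    X[i, ] <- values[i:(i + lag - 1)]
    y[i] <- values[i + lag + horizon - 1]
  }
  list(X = X, y = y, n = n)
}

# independent loop-based error metrics
oracle_rmse <- function(obs, pred) {
  acc <- 0
  for (i in seq_along(obs)) acc <- acc + (obs[i] - pred[i])^2
  sqrt(acc / length(obs))
}

oracle_mae <- function(obs, pred) {
  acc <- 0
  for (i in seq_along(obs)) acc <- acc + abs(obs[i] - pred[i])
  acc / length(obs)
}

# prepared split + scaled partitions for model tests
prepare_task <- function(series, lag, horizon, train_fraction = 0.75) {
  ds <- to_supervised(series, lag, horizon)
  parts <- chronological_split(ds, train_fraction)
  scaler <- fit_scaler(parts$train)
  list(train_raw = parts$train, test_raw = parts$test, scaler = scaler,
       train = apply_scaler(parts$train, scaler),
       test = apply_scaler(parts$test, scaler))
}
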