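# Scenario runner: the six-lag/horizon model-comparison experiment.

default_hp_for <- function(kind, lag) {
  # Modest starting configurations in the spirit of the default search
  # space; pass `hp` or `tune = TRUE` to run_scenario() for anything else.
  switch(kind,
         gru = hyper_params("gru", units = 50, lag = lag),
         lstm = hyper_params("lstm", units = 70, lag = lag),
         cnn = hyper_params("cnn", units = 170, lag = lag,
                            filters = 128, kernel = min(3L, lag)),
         cnn_lstm = hyper_params("cnn_lstm", units = c(50, 50), lag = lag,
                                 filters = 128, kernel = min(3L, lag)),
         cnn_gru = hyper_params("cnn_gru", units = c(50, 50), lag = lag,
                                filters = 128, kernel = min(3L, lag)))
}

#' Run the lag/horizon model-comparison experiment
#'
#' For every (lag, horizon) pair in the grid and every requested model
#' kind: window the series, split 75%/25% chronologically, fit the min-max
#' scaler on the training block, optionally tune the architecture, train
#' (20 epochs, batch size 1 by default), forecast the test block and score
#' RMSE/MAE in original units (mmol/L). A persistence baseline — forecast
#' the window's last observed value — is appended to each scenario as the
#' naive anchor. Pairs the series is too short for are skipped with a
#' warning.
#'
#' @param series a [cgm_series()] tibble.
#' @param grid a tibble of scenarios (`label`, `lag`, `horizon`); default
#'   [scenario_grid()].
#' @param model_kinds architectures to evaluate (default all five).
#' @param hp optional named list of [hyper_params()] overrides per kind
#'   (entries may be functions of `lag`); kinds not listed use modest
#'   defaults.
#' @param tune if `TRUE`, run [select_architecture()] per (kind, scenario)
#'   instead of fixed configurations.
#' @param n_trials,n_initial tuning budget when `tune = TRUE`.
#' @param epochs,batch_size training settings (defaults 20 and 1).
#' @param train_fraction chronological split (default 0.75).
#' @param seed integer seed; fans out deterministically over scenarios and
#'   kinds.
#' @param verbose print progress.
#' @return A tibble of class `scenario_report`: one row per (scenario,
#'   model) with columns `label`, `lag`, `horizon`, `model`, `rmse`,
#'   `mae`, `n_test` and a `hp` list-column holding the configuration
#'   used (`NULL` for the persistence baseline).
#' @export
run_scenario <- function(series, grid = scenario_grid(),
                         model_kinds = MODEL_KINDS, hp = NULL,
                         tune = FALSE, n_trials = 8, n_initial = 4,
                         epochs = 20, batch_size = 1,
                         train_fraction = 0.75, seed = 1L,
                         verbose = FALSE) {
  series <- validate_cgm(series)
  stopifnot(is.data.frame(grid),
            all(c("label", "lag", "horizon") %in% names(grid)))
  bad <- setdiff(model_kinds, MODEL_KINDS)
  if (length(bad)) {
    abort(sprintf("unknown model kind(s): %s.", paste(bad, collapse = ", ")),
          class = "glucast_param_error")
  }
  n_series <- nrow(series)
  seeds <- derive_seeds(seed, nrow(grid) * (length(model_kinds) + 1L))
  si <- 0L
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    lag <- as.integer(grid$lag[g])
    horizon <- as.integer(grid$horizon[g])
    label <- grid$label[g]
    if (n_series < lag + horizon + 3L) {
      warn(sprintf("skipping scenario %s: series too short (%d readings).",
                   label, n_series), class = "glucast_skip_warning")
      si <- si + length(model_kinds) + 1L
      next
    }
    ds <- to_supervised(series, lag, horizon)
    parts <- chronological_split(ds, train_fraction)
    scaler <- fit_scaler(parts$train)
    train_sc <- apply_scaler(parts$train, scaler)
    test_sc <- apply_scaler(parts$test, scaler)
    y_obs <- parts$test$y
    for (kind in model_kinds) {
      si <- si + 1L
      if (verbose) inform(sprintf("scenario %s: %s", label, kind))
      hp_k <- resolve_hp(hp, kind, lag)
      if (tune) {
        res <- select_architecture(parts$train, kind, n_trials = n_trials,
                                   n_initial = n_initial, epochs = epochs,
                                   batch_size = batch_size, seed = seeds[si])
        hp_k <- res$best$hyper_params
      }
      fit <- fit_forecaster(build_model(hp_k), train_sc, epochs = epochs,
                            batch_size = batch_size, seed = seeds[si])
      pred <- predict(fit, test_sc$X)
      rows[[length(rows) + 1L]] <- tibble(
        label = label, lag = lag, horizon = horizon, model = kind,
        rmse = rmse(y_obs, pred), mae = mae(y_obs, pred),
        n_test = length(y_obs), hp = list(hp_k))
    }
    si <- si + 1L
    pred_persist <- parts$test$X[, lag]
    rows[[length(rows) + 1L]] <- tibble(
      label = label, lag = lag, horizon = horizon, model = "persistence",
      rmse = rmse(y_obs, pred_persist), mae = mae(y_obs, pred_persist),
      n_test = length(y_obs), hp = list(NULL))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scenario_report", class(out))
  out
}

resolve_hp <- function(hp, kind, lag) {
  cand <- hp[[kind]]
  if (is.null(cand)) return(default_hp_for(kind, lag))
  if (is.function(cand)) cand <- cand(lag)
  stopifnot(inherits(cand, "hyper_params"))
  cand
}

#' Persistence (last-value) forecast
#'
#' The naive baseline: each window's forecast is its last observed value.
#'
#' @param X matrix of windows (original units), one per row.
#' @return Numeric vector of forecasts.
#' @export
persistence_forecast <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  X[, ncol(X)]
}

#' Write a scenario report
#'
#' `write_report_json()` emits a machine-readable report;
#' `write_report_csv()` a flat table (without the configuration column).
#'
#' @param report a `scenario_report` from [run_scenario()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "scenario_report"))
  strip <- function(hp) {
    if (is.null(hp)) return(NULL)
    hp[!vapply(hp, is.null, logical(1))]
  }
  out <- lapply(seq_len(nrow(report)), function(i) {
    list(label = report$label[i], lag = report$lag[i],
         horizon = report$horizon[i], model = report$model[i],
         rmse = report$rmse[i], mae = report$mae[i],
         n_test = report$n_test[i],
         hyper_params = strip(unclass(report$hp[[i]])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "scenario_report"))
  readr::write_csv(dplyr::select(as_tibble(report), -"hp"), path,
                   progress = FALSE)
  invisible(path)
}
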