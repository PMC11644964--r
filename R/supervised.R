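# Series-to-supervised windowing, chronological split, min-max scaling.

#' Transform a CGM series into supervised learning samples
#'
#' Builds the lag-window design matrix for direct multi-step forecasting:
#' sample `i` has predictors `X[i, ] = g[i], ..., g[i+lag-1]` (a contiguous
#' window of `lag` consecutive readings) and target
#' `y[i] = g[i+lag+horizon-1]`, the reading `horizon` steps beyond the
#' window's last element. The number of samples is
#' `N - lag - horizon + 1` for a series of length `N`.
#'
#' Lag and horizon are counts of samples (window length and steps ahead),
#' not literal minutes; at a 15-minute sampling interval one step ahead is
#' a 15-minute-ahead forecast.
#'
#' @param series a [cgm_series()] tibble.
#' @param lag window length in samples (positive integer).
#' @param horizon steps ahead of the window's last element (positive
#'   integer).
#' @param max_gap_minutes optional gap policy: when set, windows whose span
#'   (first window reading through the target) contains a timestamp gap
#'   larger than this many minutes are dropped. The default (`NULL`) treats
#'   the series as index-regular and keeps every window.
#' @return An object of class `supervised_ds`: a list with the design
#'   matrix `X` (`n_samples` by `lag`), target vector `y`, `lag`,
#'   `horizon`, a `scaled` flag and (after [apply_scaler()]) the scaler.
#' @examples
#' ds <- to_supervised(cgm_sample(), lag = 3, horizon = 1)
#' ds$X[1, ]  # 8.9 6.5 7.4
#' ds$y[1]    # 7.8
#' @export
to_supervised <- function(series, lag, horizon, max_gap_minutes = NULL) {
  series <- validate_cgm(series)
  check_number(lag, "lag", min = 1, integerish = TRUE)
  check_number(horizon, "horizon", min = 1, integerish = TRUE)
  lag <- as.integer(lag)
  horizon <- as.integer(horizon)
  n_series <- nrow(series)
  need <- lag + horizon
  if (n_series < need) {
    abort(sprintf(
      "insufficient history: %d readings given, need at least lag + horizon = %d.",
      n_series, need), class = "glucast_length_error")
  }
  v <- series$glucose
  n <- n_series - lag - horizon + 1L
  X <- matrix(0, n, lag)
  for (j in seq_len(lag)) X[, j] <- v[j:(j + n - 1L)]
  y <- v[(lag + horizon):n_series]
  keep <- rep(TRUE, n)
  if (!is.null(max_gap_minutes)) {
    check_number(max_gap_minutes, "max_gap_minutes", min = 0, strict_min = TRUE)
    gap_min <- diff(as.numeric(series$time)) / 60
    big <- gap_min > max_gap_minutes          # gap after reading i
    span <- lag + horizon - 1L                # gaps covered by one sample
    for (i in seq_len(n)) keep[i] <- !any(big[i:(i + span - 1L)])
  }
  new_supervised(X[keep, , drop = FALSE], y[keep], lag, horizon)
}

new_supervised <- function(X, y, lag, horizon, scaled = FALSE, scaler = NULL) {
  structure(list(X = X, y = y, lag = as.integer(lag),
                 horizon = as.integer(horizon),
                 scaled = scaled, scaler = scaler),
            class = "supervised_ds")
}

#' @export
print.supervised_ds <- function(x, ...) {
  cat(sprintf("<supervised_ds: %d samples, lag %d, horizon %d, %s>\n",
              nrow(x$X), x$lag, x$horizon,
              if (x$scaled) "scaled to [0,1]" else "original units"))
  invisible(x)
}

#' @export
dim.supervised_ds <- function(x) dim(x$X)

#' @rdname to_supervised
#' @param x a `supervised_ds` object (for `as_tibble`).
#' @param ... unused.
#' @export
as_tibble.supervised_ds <- function(x, ...) {
  out <- as_tibble(x$X, .name_repair = ~ paste0("lag_", rev(seq_len(x$lag))))
  out$target <- x$y
  out
}

#' Chronological train/test split
#'
#' Splits supervised samples into a training block of the first
#' `floor(train_fraction * n)` samples and a test block of the remainder.
#' No shuffling: every training sample precedes every test sample in time,
#' as required for honest forecast evaluation.
#'
#' @param ds a `supervised_ds` from [to_supervised()].
#' @param train_fraction fraction of samples for training, in (0, 1);
#'   default 0.75 (a 75%/25% split).
#' @return A list with elements `train` and `test`, both `supervised_ds`.
#' @export
chronological_split <- function(ds, train_fraction = 0.75) {
  stopifnot(inherits(ds, "supervised_ds"))
  check_number(train_fraction, "train_fraction", min = 0, max = 1,
               strict_min = TRUE, strict_max = TRUE)
  n <- nrow(ds$X)
  if (n < 2L) {
    abort("need at least 2 samples to split.", class = "glucast_length_error")
  }
  n_train <- base::floor(train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- seq_len(n_train)
  list(
    train = new_supervised(ds$X[idx, , drop = FALSE], ds$y[idx],
                           ds$lag, ds$horizon, ds$scaled, ds$scaler),
    test = new_supervised(ds$X[-idx, , drop = FALSE], ds$y[-idx],
                          ds$lag, ds$horizon, ds$scaled, ds$scaler)
  )
}

#' Min-max scaler fitted on training data only
#'
#' `fit_scaler()` records the minimum and maximum over the training
#' predictors and targets pooled; `apply_scaler()` maps
#' `x -> (x - min) / (max - min)` so the training data span `[0, 1]`;
#' `invert_scaler()` is the exact inverse. The scaler never sees test
#' values, so scaled test data may fall outside `[0, 1]` — they are not
#' clipped. Scaling test data with training statistics is what keeps the
#' evaluation leakage-free.
#'
#' @param train a `supervised_ds` holding training samples (original units).
#' @return For `fit_scaler()`, a `scaler_params` list with `min_value` and
#'   `max_value` (mmol/L).
#' @examples
#' ds <- to_supervised(cgm_sample(), 3, 1)
#' sc <- fit_scaler(ds)
#' c(sc$min_value, sc$max_value)  # 6.5 9.5
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "supervised_ds"))
  vals <- c(train$X, train$y)
  lo <- min(vals)
  hi <- max(vals)
  if (!(hi > lo)) {
    abort("degenerate scale: training data are constant.",
          class = "glucast_scale_error")
  }
  structure(list(min_value = lo, max_value = hi), class = "scaler_params")
}

#' @rdname fit_scaler
#' @param ds a `supervised_ds` to transform.
#' @param scaler a `scaler_params` object from `fit_scaler()`.
#' @export
apply_scaler <- function(ds, scaler) {
  stopifnot(inherits(ds, "supervised_ds"))
  check_scaler(scaler)
  rng <- scaler$max_value - scaler$min_value
  new_supervised((ds$X - scaler$min_value) / rng,
                 (ds$y - scaler$min_value) / rng,
                 ds$lag, ds$horizon, scaled = TRUE, scaler = scaler)
}

#' @rdname fit_scaler
#' @param values numeric vector or matrix in scaled units.
#' @export
invert_scaler <- function(values, scaler) {
  check_scaler(scaler)
  values * (scaler$max_value - scaler$min_value) + scaler$min_value
}

#' @rdname fit_scaler
#' @export
scale_values <- function(values, scaler) {
  check_scaler(scaler)
  (values - scaler$min_value) / (scaler$max_value - scaler$min_value)
}

check_scaler <- function(scaler) {
  if (!inherits(scaler, "scaler_params") ||
      !is.numeric(scaler$min_value) || !is.numeric(scaler$max_value) ||
      !(scaler$max_value > scaler$min_value)) {
    abort("invalid scaler: need max_value > min_value.",
          class = "glucast_scale_error")
  }
  invisible(scaler)
}

#' Default lag/horizon scenario grid
#'
#' The six (lag, horizon) pairs evaluated by the scenario runner, labelled
#' by the forecasting-minutes naming convention used in reports. Lags and
#' horizons are sample counts.
#'
#' @return A tibble with columns `label`, `lag`, `horizon`.
#' @export
scenario_grid <- function() {
  tibble(label = c("5 min", "15 min", "20 min", "25 min", "30 min", "60 min"),
         lag = c(3L, 10L, 13L, 18L, 20L, 30L),
         horizon = c(5L, 15L, 20L, 25L, 30L, 60L))
}
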