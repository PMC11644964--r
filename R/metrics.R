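# Forecast error metrics.

check_metric_inputs <- function(y_obs, y_pred) {
  if (length(y_obs) == 0L || length(y_pred) == 0L) {
    abort("empty input to error metric.", class = "glucast_metric_error")
  }
  if (length(y_obs) != length(y_pred)) {
    abort(sprintf("length mismatch: %d observed vs %d predicted.",
                  length(y_obs), length(y_pred)),
          class = "glucast_metric_error")
  }
  if (any(!is.finite(y_obs)) || any(!is.finite(y_pred))) {
    abort("non-finite values in error metric input.",
          class = "glucast_metric_error")
  }
}

#' Root mean square error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_{i=1}^n (y_i^{obs} - y_i^{pred})^2}}
#'
#' @param y_obs,y_pred numeric vectors of equal nonzero length.
#' @return A single number; same units as the inputs.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 5))  # sqrt(4/3)
#' @export
rmse <- function(y_obs, y_pred) {
  check_metric_inputs(y_obs, y_pred)
  sqrt(mean((y_obs - y_pred)^2))
}

#' Mean absolute error
#'
#' \eqn{\mathrm{MAE} = \frac{1}{n}\sum_{i=1}^n |y_i^{obs} - y_i^{pred}|}
#'
#' @inheritParams rmse
#' @return A single number; always `<=` the RMSE of the same vectors.
#' @examples
#' mae(c(1, 2, 3), c(1, 2, 5))  # 2/3
#' @export
mae <- function(y_obs, y_pred) {
  check_metric_inputs(y_obs, y_pred)
  mean(abs(y_obs - y_pred))
}

#' Both error metrics as a one-row tibble
#'
#' @inheritParams rmse
#' @return A tibble with columns `rmse`, `mae`, `n`.
#' @export
eval_metrics <- function(y_obs, y_pred) {
  tibble(rmse = rmse(y_obs, y_pred), mae = mae(y_obs, y_pred),
         n = length(y_obs))
}
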