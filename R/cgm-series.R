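#' Construct a CGM series
#'
#' A CGM series is a tibble with two columns, `time` (POSIXct) and `glucose`
#' (mmol/L), carrying class `cgm_ts`. Timestamps must be strictly increasing
#' and every reading must be positive and finite. All forecasting functions
#' in the package consume this container.
#'
#' @param time POSIXct vector of reading times, strictly increasing.
#' @param glucose numeric vector of glucose readings in mmol/L, same length
#'   as `time`; all values must be positive and finite.
#'
#' @return A tibble of class `cgm_ts` with columns `time` and `glucose`.
#' @examples
#' cgm_series(as.POSIXct("2020-11-03 08:00", tz = "UTC") + 900 * 0:3,
#'            c(7.1, 7.4, 8.0, 8.6))
#' @export
cgm_series <- function(time, glucose) {
  if (!inherits(time, "POSIXct")) {
    abort("`time` must be a POSIXct vector.", class = "glucast_validation_error")
  }
  if (!is.numeric(glucose)) {
    abort("`glucose` must be numeric.", class = "glucast_validation_error")
  }
  if (length(time) != length(glucose)) {
    abort("`time` and `glucose` must have the same length.",
          class = "glucast_validation_error")
  }
  out <- tibble(time = time, glucose = as.numeric(glucose))
  class(out) <- c("cgm_ts", class(tibble()))
  validate_cgm(out)
}

#' Validate a CGM series
#'
#' Checks the `cgm_ts` invariants: at least one reading, strictly increasing
#' timestamps, and positive finite glucose values.
#'
#' @param series a `cgm_ts` tibble (or any data frame with `time` and
#'   `glucose` columns).
#' @return `series`, invisibly classed as `cgm_ts`, if valid; otherwise an
#'   error of class `glucast_validation_error`.
#' @export
validate_cgm <- function(series) {
  if (!is.data.frame(series) || !all(c("time", "glucose") %in% names(series))) {
    abort("A CGM series needs `time` and `glucose` columns.",
          class = "glucast_validation_error")
  }
  n <- nrow(series)
  if (n < 1L) {
    abort("no records: a CGM series must contain at least one reading.",
          class = "glucast_validation_error")
  }
  if (anyNA(series$time)) {
    abort("CGM timestamps contain missing values.",
          class = "glucast_validation_error")
  }
  dt <- diff(as.numeric(series$time))
  if (any(dt == 0)) {
    abort("duplicate timestamps in CGM series.",
          class = "glucast_validation_error")
  }
  if (any(dt < 0)) {
    abort("CGM timestamps must be strictly increasing.",
          class = "glucast_validation_error")
  }
  g <- series$glucose
  if (any(!is.finite(g)) || any(g <= 0)) {
    abort("glucose values must be positive and finite.",
          class = "glucast_validation_error")
  }
  if (!inherits(series, "cgm_ts")) {
    class(series) <- c("cgm_ts", class(tibble()))
  }
  series
}

#' @export
print.cgm_ts <- function(x, ...) {
  cat(sprintf("<cgm_ts: %d readings, %s to %s, %.1f-%.1f mmol/L>\n",
              nrow(x),
              format(min(x$time), "%Y-%m-%d %H:%M"),
              format(max(x$time), "%Y-%m-%d %H:%M"),
              min(x$glucose), max(x$glucose)))
  NextMethod()
}
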