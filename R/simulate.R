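#' Simulation parameters for a synthetic CGM trace
#'
#' Bundles and validates the knobs of the synthetic glucose generator. The
#' generated trace is the sum of a constant baseline, a circadian sinusoid,
#' instantaneous-rise/exponential-decay meal excursions and AR(1) Gaussian
#' sensor noise, clamped to a physiological range.
#'
#' Defaults emulate a single type-1-diabetes patient wearing a 15-minute CGM
#' sensor: baseline 7 mmol/L, three daily meals with log-normal excursion
#' sizes, mildly autocorrelated noise, and readings clamped to 2-25 mmol/L.
#'
#' @param n_points number of readings to generate (positive integer).
#' @param interval_minutes sampling interval in minutes (default 15).
#' @param baseline basal glucose level, mmol/L (default 7).
#' @param circadian_amplitude amplitude of the 24 h sinusoid, mmol/L
#'   (default 0.8; peak mid-afternoon, nadir in the early morning).
#' @param meal_times character vector of daily meal clock times, `"HH:MM"`
#'   (default breakfast/lunch/dinner). Use `character(0)` for no meals.
#' @param meal_amplitude_mean,meal_amplitude_sd mean and standard deviation
#'   of the log-normal meal excursion size, mmol/L (defaults 4 and 1.5).
#' @param meal_decay_minutes exponential decay time of a meal excursion,
#'   minutes (default 90).
#' @param noise_sd innovation standard deviation of the AR(1) sensor noise,
#'   mmol/L (default 0.3).
#' @param ar_coefficient AR(1) autocorrelation of the noise, in `[0, 1)`
#'   (default 0.7).
#' @param floor,ceiling physiological clamp, mmol/L (defaults 2 and 25).
#' @param seed integer seed; identical parameters (including seed) always
#'   reproduce the identical trace.
#' @param start first timestamp (POSIXct, default 2020-11-03 00:00 UTC).
#'
#' @return A validated list of class `cgm_sim_params`.
#' @seealso [simulate_cgm()]
#' @export
cgm_sim_params <- function(n_points,
                           interval_minutes = 15,
                           baseline = 7,
                           circadian_amplitude = 0.8,
                           meal_times = c("07:30", "12:30", "18:30"),
                           meal_amplitude_mean = 4,
                           meal_amplitude_sd = 1.5,
                           meal_decay_minutes = 90,
                           noise_sd = 0.3,
                           ar_coefficient = 0.7,
                           floor = 2,
                           ceiling = 25,
                           seed = 1L,
                           start = as.POSIXct("2020-11-03 00:00:00", tz = "UTC")) {
  check_number(n_points, "n_points", min = 1, integerish = TRUE)
  check_number(interval_minutes, "interval_minutes", min = 0, strict_min = TRUE)
  check_number(baseline, "baseline")
  check_number(circadian_amplitude, "circadian_amplitude", min = 0)
  check_number(meal_amplitude_mean, "meal_amplitude_mean", min = 0)
  check_number(meal_amplitude_sd, "meal_amplitude_sd", min = 0)
  check_number(meal_decay_minutes, "meal_decay_minutes", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(ar_coefficient, "ar_coefficient", min = 0, max = 1, strict_max = TRUE)
  check_number(floor, "floor", min = 0, strict_min = TRUE)
  check_number(ceiling, "ceiling")
  check_number(seed, "seed", integerish = TRUE)
  if (!(floor < baseline && baseline < ceiling)) {
    abort("`baseline` must lie strictly between `floor` and `ceiling`.",
          class = "glucast_param_error")
  }
  if (!is.character(meal_times)) {
    abort("`meal_times` must be a character vector of HH:MM clock times.",
          class = "glucast_param_error")
  }
  meal_min <- parse_clock_minutes(meal_times)
  structure(
    list(n_points = as.integer(n_points),
         interval_minutes = interval_minutes,
         baseline = baseline,
         circadian_amplitude = circadian_amplitude,
         meal_times = meal_times,
         meal_minutes = meal_min,
         meal_amplitude_mean = meal_amplitude_mean,
         meal_amplitude_sd = meal_amplitude_sd,
         meal_decay_minutes = meal_decay_minutes,
         noise_sd = noise_sd,
         ar_coefficient = ar_coefficient,
         floor = floor,
         ceiling = ceiling,
         seed = as.integer(seed),
         start = start),
    class = "cgm_sim_params")
}

parse_clock_minutes <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  parts <- strsplit(x, ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L ||
                  anyNA(suppressWarnings(as.numeric(p))), logical(1))
  if (any(bad)) {
    abort(sprintf("`meal_times` entry %s is not an HH:MM clock time.",
                  x[which(bad)[1]]),
          class = "glucast_param_error")
  }
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}

#' Generate a synthetic CGM trace
#'
#' Simulates a glucose series at a fixed sampling interval:
#' \deqn{g(t) = \mathrm{clamp}\big(b + A\sin(2\pi (m(t)-360)/1440) +
#'   \textstyle\sum_k a_k e^{-(t-t_k)/\tau} + e_t,\; \mathrm{floor},
#'   \mathrm{ceiling}\big)}
#' where \eqn{m(t)} is the minute of day (circadian peak at 15:00, nadir at
#' 03:00), meal excursions of log-normal size \eqn{a_k} rise instantaneously
#' at each configured meal time and decay exponentially with time constant
#' \eqn{\tau}, and \eqn{e_t} is stationary AR(1) Gaussian noise.
#'
#' @param params a [cgm_sim_params()] object.
#' @return A [cgm_series()] tibble with `n_points` readings spaced
#'   `interval_minutes` apart.
#' @examples
#' flat <- cgm_sim_params(8, noise_sd = 0, circadian_amplitude = 0,
#'                        meal_times = character(0))
#' simulate_cgm(flat)$glucose  # all exactly the 7.0 baseline
#' @export
simulate_cgm <- function(params) {
  if (!inherits(params, "cgm_sim_params")) {
    abort("`params` must come from cgm_sim_params().",
          class = "glucast_param_error")
  }
  p <- params
  n <- p$n_points
  t_min <- (seq_len(n) - 1) * p$interval_minutes     # minutes since start
  start_minute <- as.numeric(format(p$start, "%H")) * 60 +
    as.numeric(format(p$start, "%M"))
  minute_of_day <- (start_minute + t_min) %% 1440

  circadian <- p$circadian_amplitude *
    sin(2 * pi * (minute_of_day - 360) / 1440)

  with_seed(p$seed, {
    meals <- meal_component(p, t_min, start_minute)
    noise <- ar1_noise(n, p$noise_sd, p$ar_coefficient)
  })

  g <- p$baseline + circadian + meals + noise
  g <- pmin(pmax(g, p$floor), p$ceiling)
  cgm_series(p$start + t_min * 60, g)
}

# Sum of exponentially decaying meal bumps over the simulated span.
meal_component <- function(p, t_min, start_minute) {
  if (length(p$meal_minutes) == 0L || p$meal_amplitude_mean == 0) {
    return(numeric(length(t_min)))
  }
  horizon <- max(t_min)
  n_days <- base::floor((start_minute + horizon) / 1440) + 1
  # meal onset times in minutes-since-start, over every simulated day
  onsets <- as.vector(outer(p$meal_minutes, (seq_len(n_days) - 1) * 1440, "+")) -
    start_minute
  onsets <- sort(onsets[onsets <= horizon])
  if (length(onsets) == 0L) return(numeric(length(t_min)))
  m <- p$meal_amplitude_mean
  s <- p$meal_amplitude_sd
  if (s > 0) {
    sdlog <- sqrt(log(1 + (s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    amps <- stats::rlnorm(length(onsets), meanlog, sdlog)
  } else {
    amps <- rep(m, length(onsets))
  }
  out <- numeric(length(t_min))
  for (k in seq_along(onsets)) {
    dt <- t_min - onsets[k]
    live <- dt >= 0
    out[live] <- out[live] + amps[k] * exp(-dt[live] / p$meal_decay_minutes)
  }
  out
}

# Stationary AR(1) Gaussian noise with innovation sd `sd`.
ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sd)
    for (i in 2:n) e[i] <- phi * e[i - 1] + innov[i - 1]
  }
  e
}

#' Remove index spans from a CGM series
#'
#' Emulates sensor dropouts by deleting readings, leaving the remaining
#' timestamps untouched (hence still strictly increasing), as in real CGM
#' exports where gaps of hours or days appear between consecutive rows.
#'
#' @param series a [cgm_series()] tibble.
#' @param gap_spans list of index spans to delete; each element is either a
#'   length-2 `c(first, last)` range or a vector of indices.
#' @return The series with those readings removed.
#' @examples
#' s <- simulate_cgm(cgm_sim_params(12))
#' nrow(inject_gaps(s, list(c(3, 5))))  # 9
#' @export
inject_gaps <- function(series, gap_spans) {
  series <- validate_cgm(series)
  if (length(gap_spans) == 0L) return(series)
  if (!is.list(gap_spans)) gap_spans <- list(gap_spans)
  n <- nrow(series)
  drop <- integer(0)
  for (span in gap_spans) {
    if (!is.numeric(span) || anyNA(span)) {
      abort("each gap span must be numeric indices.", class = "glucast_index_error")
    }
    idx <- if (length(span) == 2L) seq(span[1], span[2]) else as.integer(span)
    if (any(idx < 1L | idx > n)) {
      abort(sprintf("gap span touches index outside 1..%d.", n),
            class = "glucast_index_error")
    }
    drop <- c(drop, idx)
  }
  out <- series[-unique(drop), , drop = FALSE]
  validate_cgm(out)
}
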