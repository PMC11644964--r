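# ggplot2 displays for the package's result types.

#' Plot a CGM series
#'
#' @param object a [cgm_series()] tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cgm_ts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$glucose)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "glucose (mmol/L)") +
    ggplot2::theme_minimal()
}

#' Plot a scenario report
#'
#' Grouped bars of RMSE and MAE per model, one panel per forecasting
#' scenario.
#'
#' @param object a `scenario_report` from [run_scenario()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scenario_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), -"hp"),
    cols = c("rmse", "mae"), names_to = "metric", values_to = "value")
  long$label <- factor(long$label, levels = unique(object$label))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = NULL, y = "error (mmol/L)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a streaming forecast log
#'
#' @param object a `forecast_log` from [stream_forecast()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.forecast_log <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$event_time, y = .data$forecast)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(x = NULL, y = "forecast (mmol/L)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
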