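# broom-style tidiers.

#' Tidy a trained forecaster
#'
#' One row per weight array: the layer position, type, parameter name and
#' array shape.
#'
#' @param x a `trained_forecaster`.
#' @param ... unused.
#' @return A tibble with columns `layer`, `type`, `parameter`, `rows`,
#'   `cols`, `n`.
#' @export
tidy.trained_forecaster <- function(x, ...) {
  rows <- list()
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    for (nm in names(l$params)) {
      p <- l$params[[nm]]
      d <- dim(p) %||% c(length(p), 1L)
      rows[[length(rows) + 1L]] <- tibble(layer = i, type = l$type,
                                          parameter = nm, rows = d[1],
                                          cols = d[2], n = length(p))
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.trained_forecaster
#' @export
glance.trained_forecaster <- function(x, ...) {
  tibble(model_kind = x$hp$model_kind, lag = x$hp$lag,
         units = paste(x$hp$units, collapse = "/"),
         dropout = x$hp$dropout, reg_rate = x$hp$reg_rate,
         n_weights = n_params(x), epochs = x$epochs,
         final_loss = if (length(x$history)) tail(x$history, 1) else NA_real_,
         seed = x$seed)
}

#' Tidy a hyperparameter search result
#'
#' One row per trial, with the configuration flattened into columns.
#'
#' @param x an `hpo_result`.
#' @param ... unused.
#' @return A tibble with `trial`, `objective` and one column per
#'   hyperparameter dimension.
#' @export
tidy.hpo_result <- function(x, ...) {
  flat <- lapply(x$trials$hp, function(hp) {
    tibble(model_kind = hp$model_kind,
           units = hp$units[1],
           units2 = if (length(hp$units) > 1) hp$units[2] else NA_integer_,
           dropout = hp$dropout, reg_rate = hp$reg_rate,
           filters = hp$filters %||% NA_integer_,
           kernel = hp$kernel %||% NA_integer_)
  })
  dplyr::bind_cols(x$trials[, c("trial", "objective")],
                   dplyr::bind_rows(flat))
}

#' @rdname tidy.hpo_result
#' @export
glance.hpo_result <- function(x, ...) {
  ok <- !is.na(x$trials$objective)
  tibble(method = x$method, n_trials = nrow(x$trials),
         n_failed = sum(!ok), best_objective = x$best$objective,
         best_trial = x$best$trial, seed = x$seed)
}
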