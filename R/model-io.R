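# Plain-text persistence for trained forecasters: a directory bundle with
# the weights in weights.json and a sidecar forecaster.json holding the
# hyperparameters, scaler and training metadata.

#' Save or load a trained forecaster
#'
#' `save_forecaster()` writes a directory bundle: `forecaster.json`
#' (hyperparameters, scaler, seed, training history) and `weights.json`
#' (every layer's parameter arrays with their dimensions, at full numeric
#' precision). `load_forecaster()` rebuilds the model and restores the
#' weights; reloaded models reproduce the original predictions to within
#' double-precision serialisation (about 1e-12 relative).
#'
#' @param object a `trained_forecaster`.
#' @param dir bundle directory (created if missing).
#' @return `save_forecaster()` returns `dir` invisibly;
#'   `load_forecaster()` returns the restored `trained_forecaster`.
#' @export
save_forecaster <- function(object, dir) {
  stopifnot(inherits(object, "trained_forecaster"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hp <- object$hp
  meta <- list(
    hyper_params = list(model_kind = hp$model_kind, units = hp$units,
                        lag = hp$lag, dropout = hp$dropout,
                        reg_rate = hp$reg_rate, filters = hp$filters,
                        kernel = hp$kernel, activation = hp$activation),
    scaler = list(min_value = object$scaler$min_value,
                  max_value = object$scaler$max_value),
    seed = object$seed, epochs = object$epochs,
    batch_size = object$batch_size, history = object$history,
    stages = object$stages,
    package_version = as.character(utils::packageVersion("glucast")))
  jsonlite::write_json(meta, file.path(dir, "forecaster.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  weights <- lapply(object$layers, function(l) {
    lapply(l$params, function(p) list(dim = dim(p) %||% length(p),
                                      data = as.vector(p)))
  })
  jsonlite::write_json(weights, file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_forecaster
#' @export
load_forecaster <- function(dir) {
  meta_path <- file.path(dir, "forecaster.json")
  w_path <- file.path(dir, "weights.json")
  if (!file.exists(meta_path) || !file.exists(w_path)) {
    abort(sprintf("no forecaster bundle at %s.", dir),
          class = "glucast_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  hpj <- meta$hyper_params
  hp <- hyper_params(hpj$model_kind, units = hpj$units, lag = hpj$lag,
                     dropout = hpj$dropout, reg_rate = hpj$reg_rate,
                     filters = hpj$filters, kernel = hpj$kernel,
                     activation = hpj$activation)
  model <- build_model(hp)
  weights <- jsonlite::read_json(w_path, simplifyVector = TRUE)
  for (i in seq_along(model$layers)) {
    wl <- weights[[i]]
    params <- list()
    for (nm in names(wl)) {
      d <- unlist(wl[[nm]]$dim)
      vals <- unlist(wl[[nm]]$data)
      params[[nm]] <- if (length(d) == 2L) matrix(vals, d[1], d[2]) else vals
    }
    model$layers[[i]]$params <- params
  }
  scaler <- structure(list(min_value = meta$scaler$min_value,
                           max_value = meta$scaler$max_value),
                      class = "scaler_params")
  structure(list(hp = hp, layers = model$layers, stages = model$stages,
                 scaler = scaler, history = as.numeric(meta$history),
                 seed = as.integer(meta$seed),
                 epochs = as.integer(meta$epochs),
                 batch_size = as.integer(meta$batch_size)),
            class = "trained_forecaster")
}
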