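# Architectures, training and prediction.

MODEL_KINDS <- c("lstm", "gru", "cnn", "cnn_lstm", "cnn_gru")
CONV_KINDS <- c("cnn", "cnn_lstm", "cnn_gru")
HYBRID_KINDS <- c("cnn_lstm", "cnn_gru")

#' One model configuration
#'
#' Validates a hyperparameter set for one of the five architectures.
#'
#' @param model_kind one of `"lstm"`, `"gru"`, `"cnn"`, `"cnn_lstm"`,
#'   `"cnn_gru"`.
#' @param units recurrent/dense width. For `lstm`/`gru` a single integer
#'   (recurrent units); for `cnn` a single integer (hidden dense units);
#'   for the hybrids a pair `c(recurrent_units, dense_units)`.
#' @param lag input window length in samples.
#' @param dropout dropout rate in `[0, 1)`, applied after the recurrent
#'   layer (or after the hidden dense layer for `cnn`).
#' @param reg_rate L2 weight-decay coefficient on recurrent and dense
#'   kernels (nonnegative).
#' @param filters,kernel Conv1D filter count and kernel width; required for
#'   the convolutional kinds and forbidden otherwise. `kernel` must not
#'   exceed `lag`.
#' @param activation recurrent candidate/output activation, `"relu"`
#'   (default, ReLU throughout the network) or `"tanh"`; gate activations
#'   are always sigmoid.
#' @return A validated list of class `hyper_params`.
#' @examples
#' hyper_params("cnn_gru", units = c(150, 140), lag = 10,
#'              filters = 128, kernel = 3)
#' @export
hyper_params <- function(model_kind, units, lag, dropout = 0.2,
                         reg_rate = 0.001, filters = NULL, kernel = NULL,
                         activation = c("relu", "tanh")) {
  if (!is_scalar_string(model_kind) || !model_kind %in% MODEL_KINDS) {
    abort(sprintf("`model_kind` must be one of: %s.",
                  paste(MODEL_KINDS, collapse = ", ")),
          class = "glucast_param_error")
  }
  activation <- match.arg(activation)
  check_number(lag, "lag", min = 1, integerish = TRUE)
  n_units <- if (model_kind %in% HYBRID_KINDS) 2L else 1L
  if (!is.numeric(units) || length(units) != n_units ||
      any(units < 1) || any(units != round(units))) {
    abort(sprintf("`units` for %s must be %d positive integer(s).",
                  model_kind, n_units), class = "glucast_param_error")
  }
  check_number(dropout, "dropout", min = 0, max = 1, strict_max = TRUE)
  check_number(reg_rate, "reg_rate", min = 0)
  is_conv <- model_kind %in% CONV_KINDS
  if (is_conv) {
    if (is.null(filters) || is.null(kernel)) {
      abort(sprintf("%s requires `filters` and `kernel`.", model_kind),
            class = "glucast_param_error")
    }
    check_number(filters, "filters", min = 1, integerish = TRUE)
    check_number(kernel, "kernel", min = 1, integerish = TRUE)
    if (kernel > lag) {
      abort(sprintf("kernel (%d) must not exceed lag (%d).",
                    as.integer(kernel), as.integer(lag)),
            class = "glucast_shape_error")
    }
  } else if (!is.null(filters) || !is.null(kernel)) {
    abort(sprintf("%s takes no convolution parameters.", model_kind),
          class = "glucast_param_error")
  }
  structure(list(model_kind = model_kind,
                 units = as.integer(units),
                 lag = as.integer(lag),
                 dropout = dropout,
                 reg_rate = reg_rate,
                 filters = if (is_conv) as.integer(filters),
                 kernel = if (is_conv) as.integer(kernel),
                 activation = activation),
            class = "hyper_params")
}

#' @export
print.hyper_params <- function(x, ...) {
  conv <- if (!is.null(x$filters)) {
    sprintf(", filters %d, kernel %d", x$filters, x$kernel)
  } else ""
  cat(sprintf("<hyper_params: %s, units [%s], lag %d, dropout %g, L2 %g%s>\n",
              x$model_kind, paste(x$units, collapse = ", "), x$lag,
              x$dropout, x$reg_rate, conv))
  invisible(x)
}

#' Build an untrained forecaster
#'
#' Assembles the layer stack for the requested architecture:
#' \itemize{
#'   \item `lstm` / `gru`: recurrent layer (last hidden state) ->
#'     dropout -> linear output unit.
#'   \item `cnn`: Conv1D (ReLU) -> max-pool (width 2) -> flatten ->
#'     dense (ReLU) -> dropout -> linear output unit.
#'   \item `cnn_lstm` / `cnn_gru`: Conv1D (ReLU) -> max-pool ->
#'     recurrent layer (full sequence) -> dropout -> flatten ->
#'     dense (ReLU) -> linear output unit.
#' }
#' Convolution uses valid (no) padding; pooling halves the feature map but
#' passes length-1 maps through so short lags remain usable. Each model
#' maps one window of `lag` scaled readings to a single scalar forecast
#' (direct multi-step strategy). Weights are initialised at training time
#' so the fit seed fully determines them.
#'
#' @param hp a [hyper_params()] configuration.
#' @return An object of class `glucast_model` with an introspectable
#'   [model_stages()] sequence.
#' @export
build_model <- function(hp) {
  stopifnot(inherits(hp, "hyper_params"))
  act <- hp$activation
  kind <- hp$model_kind
  rec_type <- if (grepl("lstm", kind)) "lstm" else "gru"
  if (kind %in% c("lstm", "gru")) {
    layers <- list(
      new_layer(rec_type, units = hp$units[1], activation = act,
                return_sequences = FALSE),
      new_layer("dropout", rate = hp$dropout),
      new_layer("dense", units = 1L, activation = "linear"))
    stages <- c(rec_type, "output")
  } else if (kind == "cnn") {
    layers <- list(
      new_layer("conv1d", filters = hp$filters, kernel = hp$kernel),
      new_layer("maxpool"),
      new_layer("flatten"),
      new_layer("dense", units = hp$units[1], activation = "relu"),
      new_layer("dropout", rate = hp$dropout),
      new_layer("dense", units = 1L, activation = "linear"))
    stages <- c("conv1d", "maxpool", "flatten", "dense", "output")
  } else {
    layers <- list(
      new_layer("conv1d", filters = hp$filters, kernel = hp$kernel),
      new_layer("maxpool"),
      new_layer(rec_type, units = hp$units[1], activation = act,
                return_sequences = TRUE),
      new_layer("dropout", rate = hp$dropout),
      new_layer("flatten"),
      new_layer("dense", units = hp$units[2], activation = "relu"),
      new_layer("dense", units = 1L, activation = "linear"))
    stages <- c("conv1d", "maxpool", rec_type, "flatten", "dense", "output")
  }
  structure(list(hp = hp, layers = layers, stages = stages,
                 initialized = FALSE),
            class = "glucast_model")
}

#' @rdname build_model
#' @param model a `glucast_model` or `trained_forecaster`.
#' @return For `model_stages()`, the character vector of principal pipeline
#'   stages in order (dropout, a training-time regulariser, is not a
#'   stage).
#' @export
model_stages <- function(model) {
  stopifnot(inherits(model, c("glucast_model", "trained_forecaster")))
  model$stages
}

# feature-map length after conv (+pool) ahead of the flatten/recurrent part
conv_out_length <- function(lag, kernel) {
  t_conv <- lag - kernel + 1L
  max(1L, t_conv %/% 2L)
}

# initialise every layer's parameters, tracking input widths through the
# stack; consumes the active RNG stream
init_model_params <- function(model) {
  hp <- model$hp
  width <- 1L                # channels/features entering the next layer
  t_len <- hp$lag
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    model$layers[[i]] <- init_layer(layer, width)
    width <- switch(layer$type,
                    conv1d = {t_len <- t_len - layer$config$kernel + 1L
                              layer$config$filters},
                    maxpool = {t_len <- max(1L, t_len %/% 2L)
                               width},
                    gru = ,
                    lstm = {if (!layer$config$return_sequences) t_len <- 1L
                            layer$config$units},
                    flatten = {w <- t_len * width
                               t_len <- 1L
                               w},
                    dense = layer$config$units,
                    width)
  }
  model$initialized <- TRUE
  model
}

n_params <- function(model) {
  sum(vapply(model$layers,
             function(l) sum(vapply(l$params, length, integer(1), USE.NAMES = FALSE)),
             numeric(1)))
}

# forward pass for one window (lag x 1 matrix); returns scalar + caches
model_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- nn_forward(layers[[i]], x, training)
    x <- step$out
    caches[[i]] <- step$cache
  }
  list(yhat = as.numeric(x), caches = caches)
}

# backward pass; returns per-layer grads (including L2 terms)
model_backward <- function(layers, caches, dyhat, reg_rate) {
  grads <- vector("list", length(layers))
  dout <- matrix(dyhat, 1, 1)
  for (i in rev(seq_along(layers))) {
    bk <- nn_backward(layers[[i]], dout, caches[[i]])
    grads[[i]] <- bk$grads
    dout <- bk$dx
  }
  if (reg_rate > 0) {
    for (i in seq_along(layers)) {
      for (nm in l2_param_names(layers[[i]])) {
        grads[[i]][[nm]] <- grads[[i]][[nm]] +
          2 * reg_rate * layers[[i]]$params[[nm]]
      }
    }
  }
  grads
}

l2_penalty <- function(layers, reg_rate) {
  if (reg_rate == 0) return(0)
  tot <- 0
  for (l in layers) {
    for (nm in l2_param_names(l)) tot <- tot + sum(l$params[[nm]]^2)
  }
  reg_rate * tot
}

#' Train a forecaster
#'
#' Fits the model by stochastic gradient descent with the Adam optimizer on
#' mean-squared-error loss (plus the L2 penalty), batch size 1 and 20
#' epochs by default. Training order is reshuffled each epoch from the
#' seeded RNG stream; the same seed, data and configuration reproduce the
#' identical loss history and weights.
#'
#' @param model an untrained model from [build_model()].
#' @param train_ds a scaled `supervised_ds` (see [apply_scaler()]) whose
#'   window width equals the model's `lag`.
#' @param epochs number of passes over the training data (default 20).
#'   `epochs = 0` initialises weights and returns without training.
#' @param batch_size gradient-averaging batch size (default 1).
#' @param seed integer seed controlling weight initialisation, shuffling
#'   and dropout.
#' @param learning_rate Adam step size (default 0.001).
#' @param verbose print per-epoch loss.
#' @return A `trained_forecaster`: the fitted layers plus the
#'   hyperparameters, the scaler the data were prepared with, the per-epoch
#'   mean training loss (`history`) and the seed.
#' @export
fit_forecaster <- function(model, train_ds, epochs = 20, batch_size = 1,
                           seed = 1L, learning_rate = 0.001,
                           verbose = FALSE) {
  stopifnot(inherits(model, "glucast_model"),
            inherits(train_ds, "supervised_ds"))
  check_number(epochs, "epochs", min = 0, integerish = TRUE)
  check_number(batch_size, "batch_size", min = 1, integerish = TRUE)
  if (!train_ds$scaled) {
    abort("training data must be scaled; see fit_scaler()/apply_scaler().",
          class = "glucast_scale_error")
  }
  if (ncol(train_ds$X) != model$hp$lag) {
    abort(sprintf("window width %d does not match model lag %d.",
                  ncol(train_ds$X), model$hp$lag),
          class = "glucast_shape_error")
  }
  n <- nrow(train_ds$X)
  reg <- model$hp$reg_rate
  history <- numeric(0)
  with_seed(seed, {
    model <- init_model_params(model)
    if (epochs > 0) {
      opt <- adam_init(model$layers, learning_rate)
      for (ep in seq_len(epochs)) {
        order_idx <- sample.int(n)
        ep_loss <- 0
        b <- 1L
        while (b <= n) {
          batch <- order_idx[b:min(b + batch_size - 1L, n)]
          acc <- NULL
          for (s in batch) {
            x <- matrix(train_ds$X[s, ], ncol = 1)
            fw <- model_forward(model$layers, x, training = TRUE)
            err <- fw$yhat - train_ds$y[s]
            ep_loss <- ep_loss + err^2
            g <- model_backward(model$layers, fw$caches, 2 * err, reg)
            acc <- if (is.null(acc)) g else add_grads(acc, g)
          }
          if (length(batch) > 1L) acc <- scale_grads(acc, 1 / length(batch))
          upd <- adam_step(opt, model$layers, acc)
          opt <- upd$opt
          model$layers <- upd$layers
          b <- b + batch_size
        }
        mean_loss <- ep_loss / n + l2_penalty(model$layers, reg)
        if (!is.finite(mean_loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d.", ep),
                class = "glucast_divergence_error")
        }
        history <- c(history, mean_loss)
        if (verbose) inform(sprintf("epoch %d/%d loss %.6f", ep, epochs, mean_loss))
      }
    }
  })
  structure(list(hp = model$hp, layers = model$layers, stages = model$stages,
                 scaler = train_ds$scaler, history = history,
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "trained_forecaster")
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

scale_grads <- function(g, f) {
  for (i in seq_along(g)) {
    for (nm in names(g[[i]])) g[[i]][[nm]] <- g[[i]][[nm]] * f
  }
  g
}

adam_init <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state <- lapply(layers, function(l) {
    lapply(l$params, function(p) list(m = array(0, dim(p) %||% length(p)),
                                      v = array(0, dim(p) %||% length(p))))
  })
  list(state = state, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L)
}

adam_step <- function(opt, layers, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      st <- opt$state[[i]][[nm]]
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
      opt$state[[i]][[nm]] <- st
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        opt$lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
    }
  }
  list(opt = opt, layers = layers)
}

#' Forecast from trained weights
#'
#' Runs inference on windows that were scaled with the model's own scaler
#' and returns forecasts in original units (mmol/L) after inverse scaling.
#' Dropout is inactive at inference, so repeated calls are identical.
#'
#' @param object a `trained_forecaster`.
#' @param X matrix of scaled windows (rows) with width equal to the model
#'   lag, or a single window as a vector.
#' @param ... unused.
#' @return Numeric vector of forecasts, one per window, in mmol/L.
#' @export
predict.trained_forecaster <- function(object, X, ...) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != object$hp$lag) {
    abort(sprintf("window width %d does not match model lag %d.",
                  ncol(X), object$hp$lag),
          class = "glucast_shape_error")
  }
  raw <- vapply(seq_len(nrow(X)), function(i) {
    model_forward(object$layers, matrix(X[i, ], ncol = 1))$yhat
  }, numeric(1))
  invert_scaler(raw, object$scaler)
}

#' @export
print.trained_forecaster <- function(x, ...) {
  cat(sprintf("<trained_forecaster: %s, lag %d, %d weights, %d epoch(s)%s>\n",
              x$hp$model_kind, x$hp$lag, n_params(x),
              x$epochs,
              if (length(x$history)) sprintf(", final loss %.4g", tail(x$history, 1))
              else ""))
  invisible(x)
}
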