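# Architecture construction, gradients, training behaviour.

test_that("hyperparameter validation enforces the architecture contracts", {
  expect_error(hyper_params("gru", units = 50, lag = 10, filters = 128,
                            kernel = 3),
               "no convolution", class = "glucast_param_error")
  expect_error(hyper_params("cnn_gru", units = c(50, 50), lag = 3,
                            filters = 128, kernel = 4),
               "kernel", class = "glucast_shape_error")
  expect_error(hyper_params("cnn_gru", units = 50, lag = 10, filters = 128,
                            kernel = 3),
               "2 positive integer", class = "glucast_param_error")
  expect_error(hyper_params("cnn", units = 170, lag = 10),
               "requires", class = "glucast_param_error")
  hp <- hyper_params("gru", units = 50, lag = 10)
  expect_null(hp$filters)
  expect_null(hp$kernel)
})

test_that("each architecture exposes its pipeline stage sequence", {
  expect_equal(model_stages(build_model(tiny_hp("gru"))), c("gru", "output"))
  expect_equal(model_stages(build_model(tiny_hp("lstm"))), c("lstm", "output"))
  expect_equal(model_stages(build_model(tiny_hp("cnn"))),
               c("conv1d", "maxpool", "flatten", "dense", "output"))
  expect_equal(model_stages(build_model(tiny_hp("cnn_gru"))),
               c("conv1d", "maxpool", "gru", "flatten", "dense", "output"))
  expect_equal(model_stages(build_model(tiny_hp("cnn_lstm"))),
               c("conv1d", "maxpool", "lstm", "flatten", "dense", "output"))
})

test_that("backpropagation matches central finite differences", {
  check_grads <- function(hp, seed = 42, eps = 1e-5) {
    m <- build_model(hp)
    set.seed(seed)
    m <- glucast:::init_model_params(m)
    x <- matrix(runif(hp$lag, 0.1, 0.9), ncol = 1)
    y <- 0.5
    loss_fn <- function(layers) {
      fw <- glucast:::model_forward(layers, x)
      (fw$yhat - y)^2 + glucast:::l2_penalty(layers, hp$reg_rate)
    }
    fw <- glucast:::model_forward(m$layers, x)
    g <- glucast:::model_backward(m$layers, fw$caches, 2 * (fw$yhat - y),
                                  hp$reg_rate)
    worst <- 0
    for (i in seq_along(m$layers)) {
      for (nm in names(m$layers[[i]]$params)) {
        p <- m$layers[[i]]$params[[nm]]
        for (j in sample(length(p), min(4, length(p)))) {
          l2 <- m$layers
          l2[[i]]$params[[nm]][j] <- p[j] + eps
          up <- loss_fn(l2)
          l2[[i]]$params[[nm]][j] <- p[j] - eps
          dn <- loss_fn(l2)
          num <- (up - dn) / (2 * eps)
          ana <- g[[i]][[nm]][j]
          worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
        }
      }
    }
    worst
  }
  hps <- list(
    hyper_params("gru", units = 5, lag = 8, dropout = 0, reg_rate = 0.01),
    hyper_params("lstm", units = 5, lag = 8, dropout = 0, reg_rate = 0.01),
    hyper_params("gru", units = 5, lag = 8, dropout = 0, reg_rate = 0,
                 activation = "tanh"),
    hyper_params("cnn", units = 6, lag = 8, dropout = 0, reg_rate = 0.01,
                 filters = 4, kernel = 3),
    hyper_params("cnn_gru", units = c(5, 4), lag = 8, dropout = 0,
                 reg_rate = 0.01, filters = 4, kernel = 3),
    hyper_params("cnn_lstm", units = c(5, 4), lag = 8, dropout = 0,
                 reg_rate = 0.01, filters = 4, kernel = 3))
  for (hp in hps) expect_lt(check_grads(hp), 1e-5)
})

test_that("recurrent gate activations stay in (0,1) on random inputs", {
  set.seed(7)
  for (type in c("gru", "lstm")) {
    layer <- glucast:::new_layer(type, units = 6, activation = "tanh",
                                 return_sequences = TRUE)
    layer <- glucast:::init_layer(layer, 3L)
    x <- matrix(rnorm(30), 10, 3)
    fw <- glucast:::nn_forward(layer, x)
    for (st in fw$cache$steps) {
      gates <- if (type == "gru") c(st$z, st$r) else c(st$i, st$f, st$o)
      expect_true(all(gates > 0 & gates < 1))
      cand <- if (type == "gru") st$hh else st$g
      expect_true(all(cand > -1 & cand < 1))
    }
  }
})

test_that("max pooling halves feature maps and ReLU output is nonnegative", {
  set.seed(8)
  layer <- glucast:::new_layer("maxpool")
  for (t_in in c(2, 5, 8, 9)) {
    x <- matrix(rnorm(t_in * 3), t_in, 3)
    out <- glucast:::nn_forward(layer, x)$out
    expect_equal(nrow(out), t_in %/% 2)
  }
  # length-1 maps pass through so the shortest lags stay usable
  x1 <- matrix(rnorm(3), 1, 3)
  expect_equal(glucast:::nn_forward(layer, x1)$out, x1)
  conv <- glucast:::init_layer(glucast:::new_layer("conv1d", filters = 4,
                                                   kernel = 3), 1L)
  out <- glucast:::nn_forward(conv, matrix(rnorm(8), ncol = 1))$out
  expect_true(all(out >= 0))
  expect_equal(dim(out), c(6, 4))
})

test_that("training is seed-reproducible and epochs=0 is a no-op fit", {
  task <- prepare_task(ar_series(120, seed = 3), lag = 6, horizon = 1)
  hp <- tiny_hp("gru", lag = 6)
  f1 <- fit_forecaster(build_model(hp), task$train, epochs = 3, seed = 11)
  f2 <- fit_forecaster(build_model(hp), task$train, epochs = 3, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, task$test$X), predict(f2, task$test$X))
  f3 <- fit_forecaster(build_model(hp), task$train, epochs = 3, seed = 12)
  expect_false(identical(f1$history, f3$history))
  f0 <- fit_forecaster(build_model(hp), task$train, epochs = 0, seed = 11)
  expect_length(f0$history, 0)
  expect_length(predict(f0, task$test$X), nrow(task$test$X))
})

test_that("repeated inference is identical (dropout inactive at predict)", {
  task <- prepare_task(ar_series(120, seed = 4), lag = 6, horizon = 1)
  hp <- hyper_params("cnn_gru", units = c(8, 6), lag = 6, dropout = 0.5,
                     filters = 6, kernel = 3)
  fit <- fit_forecaster(build_model(hp), task$train, epochs = 2, seed = 1)
  p1 <- predict(fit, task$test$X)
  p2 <- predict(fit, task$test$X)
  expect_identical(p1, p2)
  expect_length(predict(fit, task$test$X[1, ]), 1)
  expect_error(predict(fit, task$test$X[, 1:4]), "lag",
               class = "glucast_shape_error")
})

test_that("loss decreases on a learnable constant target", {
  task <- prepare_task(ar_series(100, seed = 5), lag = 5, horizon = 1)
  const <- glucast:::new_supervised(task$train$X, rep(0.5, nrow(task$train$X)),
                                    5L, 1L, scaled = TRUE,
                                    scaler = task$scaler)
  fit <- fit_forecaster(build_model(tiny_hp("gru", lag = 5)), const,
                        epochs = 10, seed = 2)
  expect_lt(tail(fit$history, 1), fit$history[1])
})

test_that("parameter count grows with units and filters", {
  count <- function(hp) {
    m <- build_model(hp)
    set.seed(1)
    glucast:::n_params(glucast:::init_model_params(m))
  }
  small <- count(hyper_params("cnn_gru", units = c(8, 6), lag = 10,
                              filters = 4, kernel = 3))
  wider <- count(hyper_params("cnn_gru", units = c(16, 6), lag = 10,
                              filters = 4, kernel = 3))
  more_filters <- count(hyper_params("cnn_gru", units = c(8, 6), lag = 10,
                                     filters = 8, kernel = 3))
  expect_gt(wider, small)
  expect_gt(more_filters, small)
  for (kind in c("gru", "lstm", "cnn")) {
    expect_gt(count(switch(kind,
                           cnn = hyper_params("cnn", units = 32, lag = 10,
                                              filters = 4, kernel = 3),
                           hyper_params(kind, units = 32, lag = 10))),
              count(tiny_hp(kind)))
  }
})

test_that("diverging training reports the epoch", {
  task <- prepare_task(ar_series(80, seed = 6), lag = 5, horizon = 1)
  hp <- hyper_params("gru", units = 8, lag = 5, dropout = 0, reg_rate = 0)
  expect_error(
    fit_forecaster(build_model(hp), task$train, epochs = 3, seed = 1,
                   learning_rate = 1e200),
    "epoch", class = "glucast_divergence_error")
})

test_that("unscaled data or mismatched window width are rejected", {
  task <- prepare_task(ar_series(100, seed = 7), lag = 5, horizon = 1)
  hp <- tiny_hp("gru", lag = 5)
  expect_error(fit_forecaster(build_model(hp), task$train_raw),
               class = "glucast_scale_error")
  hp10 <- tiny_hp("gru", lag = 10)
  expect_error(fit_forecaster(build_model(hp10), task$train),
               class = "glucast_shape_error")
})

test_that("a saved forecaster reloads and predicts identically", {
  task <- prepare_task(ar_series(120, seed = 8), lag = 6, horizon = 2)
  fit <- fit_forecaster(build_model(tiny_hp("cnn_lstm", lag = 6)),
                        task$train, epochs = 2, seed = 3)
  dir <- tempfile("bundle")
  save_forecaster(fit, dir)
  back <- load_forecaster(dir)
  expect_equal(predict(back, task$test$X), predict(fit, task$test$X),
               tolerance = 1e-10)
  expect_equal(back$hp, fit$hp)
  expect_equal(back$scaler$min_value, fit$scaler$min_value)
  expect_equal(back$history, fit$history)
  expect_equal(model_stages(back), model_stages(fit))
})

test_that("tidy and glance summarise a fitted forecaster", {
  task <- prepare_task(ar_series(100, seed = 9), lag = 5, horizon = 1)
  fit <- fit_forecaster(build_model(tiny_hp("gru", lag = 5)), task$train,
                        epochs = 2, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("layer", "type", "parameter", "n") %in% names(td)))
  expect_equal(sum(td$n), glucast:::n_params(fit))
  gl <- glance(fit)
  expect_equal(gl$model_kind, "gru")
  expect_equal(gl$epochs, 2L)
})
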