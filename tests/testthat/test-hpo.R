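# Hyperparameter search: sampling, surrogate-guided optimization.

toy_space <- function() {
  search_space("cnn_gru", lag = 10,
               units = c(190L, 200L, 210L), units2 = 100L,
               dropout_range = c(0.2, 0.2), reg_rate = 0.01,
               filters = 128L, kernel = c(3L, 4L))
}

toy_objective <- function(hp) {
  (hp$units[1] - 200)^2 + 10 * abs(hp$kernel - 3)
}

test_that("space sampling stays inside the declared sets", {
  sp <- search_space("cnn_gru", lag = 10)
  draws <- lapply(1:500, function(s) sample_space(sp, s))
  expect_setequal(unique(vapply(draws, function(h) h$reg_rate, numeric(1))),
                  c(0.01, 0.05, 0.005, 0.001))
  expect_setequal(unique(vapply(draws, function(h) h$kernel, integer(1))),
                  c(3L, 4L))
  expect_setequal(unique(vapply(draws, function(h) h$filters, integer(1))),
                  c(200L, 128L, 250L))
  units <- vapply(draws, function(h) h$units[1], integer(1))
  expect_true(all(units %in% seq(50L, 500L, 10L)))
  dropout <- vapply(draws, function(h) h$dropout, numeric(1))
  expect_true(all(dropout >= 0.1 & dropout <= 0.9))
  # deterministic under seed
  expect_identical(sample_space(sp, 5), sample_space(sp, 5))
  # kernels that cannot fit the lag are excluded up front
  sp3 <- search_space("cnn_gru", lag = 3)
  expect_equal(sp3$kernel, 3L)
  # degenerate space yields its single configuration
  one <- sample_space(toy_space(), 1)
  expect_equal(one$units[2], 100L)
  expect_equal(one$dropout, 0.2)
})

test_that("with budget covering the toy grid, optimization finds the exhaustive optimum", {
  # exhaustive oracle over the 3 x 2 grid
  grid_vals <- expand.grid(units = c(190, 200, 210), kernel = c(3, 4))
  truth <- min((grid_vals$units - 200)^2 + 10 * abs(grid_vals$kernel - 3))
  res <- bayes_optimize(toy_objective, toy_space(), n_trials = 6,
                        n_initial = 2, seed = 3)
  expect_equal(nrow(res$trials), 6)
  expect_equal(res$best$objective, truth)
  expect_equal(res$best$hyper_params$units[1], 200L)
  expect_equal(res$best$hyper_params$kernel, 3L)
  # best bookkeeping: min over trials, monotone best-so-far
  expect_equal(res$best$objective, min(res$trials$objective, na.rm = TRUE))
  expect_true(all(diff(cummin(res$trials$objective)) <= 0))
})

test_that("surrogate-guided search beats random search in the median", {
  sp <- search_space("cnn_gru", lag = 10)
  f <- function(hp) {
    (hp$units[1] - 200)^2 / 1000 + 10 * abs(hp$kernel - 3) +
      (hp$units[2] - 100)^2 / 1000 + hp$dropout
  }
  bo <- vapply(1:20, function(s)
    bayes_optimize(f, sp, n_trials = 20, n_initial = 5, seed = s)$best$objective,
    numeric(1))
  rs <- vapply(1:20, function(s)
    random_search(f, sp, n_trials = 20, seed = s)$best$objective, numeric(1))
  expect_lte(median(bo), median(rs))
})

test_that("failed trials are excluded and a constant objective is handled", {
  sp <- toy_space()
  flaky <- function(hp) if (hp$kernel == 4) stop("boom") else toy_objective(hp)
  res <- bayes_optimize(flaky, sp, n_trials = 6, n_initial = 2, seed = 1)
  expect_true(any(is.na(res$trials$objective)))
  expect_false(is.na(res$best$objective))
  expect_equal(res$best$hyper_params$kernel, 3L)
  const <- function(hp) 1.5
  res2 <- bayes_optimize(const, sp, n_trials = 4, n_initial = 2, seed = 2)
  expect_equal(res2$best$objective, 1.5)
  all_fail <- function(hp) NaN
  expect_error(bayes_optimize(all_fail, sp, n_trials = 3, n_initial = 2,
                              seed = 1),
               "all trials failed", class = "glucast_hpo_error")
})

test_that("architecture selection returns reproducible trial sequences", {
  series <- ar_series(150, seed = 10)
  ds <- to_supervised(series, 5, 1)
  parts <- chronological_split(ds, 0.75)
  sp <- search_space("gru", lag = 5, units = c(4L, 8L),
                     dropout_range = c(0.1, 0.1), reg_rate = 0.001)
  res <- select_architecture(parts$train, "gru", n_trials = 2, n_initial = 2,
                             epochs = 2, seed = 5, space = sp)
  expect_equal(nrow(res$trials), 2)
  expect_equal(res$best$objective, min(res$trials$objective))
  expect_gte(res$best$objective, 0)
  res2 <- select_architecture(parts$train, "gru", n_trials = 2, n_initial = 2,
                              epochs = 2, seed = 5, space = sp)
  expect_identical(tidy(res)$objective, tidy(res2)$objective)
  expect_identical(tidy(res)$units, tidy(res2)$units)
  # single-trial budget degenerates to the one random draw
  res1 <- select_architecture(parts$train, "gru", n_trials = 1, epochs = 0,
                              seed = 6, space = sp, method = "random")
  expect_equal(nrow(res1$trials), 1)
  expect_equal(res1$best$objective, res1$trials$objective[1])
})

test_that("search results serialise to JSON", {
  res <- bayes_optimize(toy_objective, toy_space(), n_trials = 4,
                        n_initial = 2, seed = 4)
  path <- tempfile(fileext = ".json")
  write_hpo_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(back$best$objective, res$best$objective)
  expect_equal(length(back$trials), nrow(res$trials))
  gl <- glance(res)
  expect_equal(gl$best_objective, res$best$objective)
})
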