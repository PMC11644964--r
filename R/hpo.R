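# Hyperparameter search: random sampling and Bayesian optimization with a
# Gaussian-process surrogate and expected-improvement acquisition.

#' Hyperparameter search space
#'
#' The default space per architecture: units from 50 to 500 in steps of 10
#' (each width dimension), dropout uniform in `[0.1, 0.9]`, L2 coefficient
#' from `{0.01, 0.05, 0.005, 0.001}`, and for convolutional kinds filters
#' from `{200, 128, 250}` and kernel from `{3, 4}` (restricted to kernels
#' that fit the lag). Any dimension can be overridden, e.g. to build a
#' degenerate or toy space.
#'
#' @param model_kind one of the five architecture names.
#' @param lag input window length the sampled configurations will use.
#' @param units,units2 allowed width values (`units2` only for hybrids).
#' @param dropout_range length-2 numeric range for the dropout rate; equal
#'   endpoints pin it.
#' @param reg_rate,filters,kernel allowed categorical values.
#' @return A list of class `search_space`.
#' @export
search_space <- function(model_kind, lag,
                         units = seq(50L, 500L, 10L),
                         units2 = seq(50L, 500L, 10L),
                         dropout_range = c(0.1, 0.9),
                         reg_rate = c(0.01, 0.05, 0.005, 0.001),
                         filters = c(200L, 128L, 250L),
                         kernel = c(3L, 4L)) {
  if (!model_kind %in% MODEL_KINDS) {
    abort(sprintf("`model_kind` must be one of: %s.",
                  paste(MODEL_KINDS, collapse = ", ")),
          class = "glucast_param_error")
  }
  check_number(lag, "lag", min = 1, integerish = TRUE)
  is_conv <- model_kind %in% CONV_KINDS
  if (is_conv) {
    kernel <- kernel[kernel <= lag]
    if (length(kernel) == 0L) {
      abort("no kernel value in the space fits the lag.",
            class = "glucast_shape_error")
    }
  }
  structure(list(model_kind = model_kind, lag = as.integer(lag),
                 units = as.integer(units),
                 units2 = if (model_kind %in% HYBRID_KINDS) as.integer(units2),
                 dropout_range = dropout_range,
                 reg_rate = reg_rate,
                 filters = if (is_conv) as.integer(filters),
                 kernel = if (is_conv) as.integer(kernel)),
            class = "search_space")
}

#' Draw one configuration uniformly from a search space
#'
#' Each dimension is sampled independently and uniformly (widths and
#' categorical values from their listed sets, dropout from its continuous
#' range). Deterministic under `seed`.
#'
#' @param space a [search_space()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [hyper_params()] configuration inside the space.
#' @export
sample_space <- function(space, seed = NULL) {
  stopifnot(inherits(space, "search_space"))
  draw <- function() {
    units <- sample_one(space$units)
    if (!is.null(space$units2)) units <- c(units, sample_one(space$units2))
    dr <- space$dropout_range
    hyper_params(space$model_kind, units = units, lag = space$lag,
                 dropout = if (dr[1] == dr[2]) dr[1] else runif(1, dr[1], dr[2]),
                 reg_rate = sample_one(space$reg_rate),
                 filters = if (!is.null(space$filters)) sample_one(space$filters),
                 kernel = if (!is.null(space$kernel)) sample_one(space$kernel))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

sample_one <- function(values) {
  if (length(values) == 1L) values else values[sample.int(length(values), 1L)]
}

# numeric encoding of a configuration for the GP surrogate: widths and
# dropout scaled to [0,1], categorical dimensions one-hot
encode_hp <- function(hp, space) {
  scale01 <- function(x, values) {
    rng <- range(values)
    if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0
  }
  onehot <- function(x, values) as.numeric(values == x)
  enc <- scale01(hp$units[1], space$units)
  if (!is.null(space$units2)) enc <- c(enc, scale01(hp$units[2], space$units2))
  dr <- space$dropout_range
  enc <- c(enc, if (dr[2] > dr[1]) (hp$dropout - dr[1]) / (dr[2] - dr[1]) else 0)
  enc <- c(enc, onehot(hp$reg_rate, space$reg_rate))
  if (!is.null(space$filters)) enc <- c(enc, onehot(hp$filters, space$filters))
  if (!is.null(space$kernel)) enc <- c(enc, onehot(hp$kernel, space$kernel))
  enc
}

# ---- Gaussian-process surrogate (RBF kernel, fixed median lengthscale) --

gp_fit <- function(X, y, noise = 1e-4) {
  mu <- mean(y)
  sdv <- sd(y)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ys <- (y - mu) / sdv
  d2 <- as.matrix(stats::dist(X))^2
  nz <- d2[upper.tri(d2)][d2[upper.tri(d2)] > 0]
  ell2 <- if (length(nz)) median(nz) else 1
  K <- exp(-0.5 * d2 / ell2)
  L <- chol(K + diag(noise + 1e-8, nrow(X)))
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, ell2 = ell2, mu = mu, sd = sdv,
       noise = noise)
}

gp_predict <- function(fit, Xnew) {
  cross <- -2 * Xnew %*% t(fit$X)
  cross <- sweep(cross, 1, rowSums(Xnew^2), "+")
  cross <- sweep(cross, 2, rowSums(fit$X^2), "+")
  Ks <- exp(-0.5 * pmax(cross, 0) / fit$ell2)
  mu_s <- as.vector(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(Ks))
  var_s <- pmax(1 - colSums(v^2), 0)
  list(mean = fit$mu + fit$sd * mu_s, sd = fit$sd * sqrt(var_s))
}

# expected improvement for minimization
expected_improvement <- function(mu, s, best) {
  out <- pmax(best - mu, 0)
  pos <- s > 0
  z <- (best[1] - mu[pos]) / s[pos]
  out[pos] <- (best - mu[pos]) * pnorm(z) + s[pos] * dnorm(z)
  out
}

new_hpo_result <- function(trials, space, method, seed) {
  ok <- !is.na(trials$objective)
  if (!any(ok)) {
    abort("all trials failed.", class = "glucast_hpo_error")
  }
  ibest <- which(trials$objective == min(trials$objective[ok]))[1]
  structure(list(best = list(hyper_params = trials$hp[[ibest]],
                             objective = trials$objective[ibest],
                             trial = trials$trial[ibest]),
                 trials = trials, space = space, method = method,
                 seed = seed),
            class = "hpo_result")
}

#' @export
print.hpo_result <- function(x, ...) {
  cat(sprintf("<hpo_result: %s, %d trial(s), best objective %.6g at trial %d>\n",
              x$method, nrow(x$trials), x$best$objective, x$best$trial))
  print(x$best$hyper_params)
  invisible(x)
}

run_trial <- function(objective, hp) {
  val <- tryCatch(objective(hp), error = function(e) NA_real_)
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) NA_real_
  else as.numeric(val)
}

#' Random-search baseline
#'
#' Evaluates `n_trials` configurations drawn uniformly from the space.
#'
#' @param objective function mapping a [hyper_params()] configuration to a
#'   single number to minimise (e.g. validation RMSE). Trials that error or
#'   return a non-finite value are recorded as failed and excluded.
#' @param space a [search_space()].
#' @param n_trials evaluation budget.
#' @param seed integer seed.
#' @return An `hpo_result`: the best trial, the full trial table (a tibble
#'   with a `hp` list-column), and the space searched.
#' @export
random_search <- function(objective, space, n_trials = 20, seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  check_number(n_trials, "n_trials", min = 1, integerish = TRUE)
  seeds <- derive_seeds(seed, n_trials)
  hps <- lapply(seeds, function(s) sample_space(space, s))
  objs <- vapply(hps, function(hp) run_trial(objective, hp), numeric(1))
  trials <- tibble(trial = seq_len(n_trials), objective = objs, hp = hps)
  new_hpo_result(trials, space, "random", seed)
}

#' Bayesian hyperparameter optimization
#'
#' Sequential model-based search: after `n_initial` uniform random trials,
#' a Gaussian-process surrogate (RBF kernel over the numerically encoded
#' configuration space, fixed median-heuristic lengthscale) is refitted to
#' all successful trials, and the next configuration is the
#' expected-improvement maximiser over a random candidate pool, skipping
#' configurations already evaluated. Stops early if the space is
#' exhausted; with a budget covering a small discrete space this reduces
#' to exhaustive search.
#'
#' @inheritParams random_search
#' @param n_initial number of random warm-up trials (at least 2).
#' @param n_candidates size of the random candidate pool scored by
#'   expected improvement at each step.
#' @return An `hpo_result` (see [random_search()]).
#' @export
bayes_optimize <- function(objective, space, n_trials = 20, n_initial = 5,
                           seed = 1L, n_candidates = 256L) {
  stopifnot(inherits(space, "search_space"))
  check_number(n_initial, "n_initial", min = 2, integerish = TRUE)
  check_number(n_trials, "n_trials", min = n_initial, integerish = TRUE)
  seeds <- derive_seeds(seed, 2L * n_trials + 1L)
  hps <- list()
  objs <- numeric(0)
  enc <- NULL
  seen <- character(0)
  propose_unseen <- function(s, pool_n) {
    # draw a pool, drop already-evaluated configurations
    with_seed(s, {
      pool <- replicate(pool_n, sample_space(space), simplify = FALSE)
    })
    keys <- vapply(pool, function(h)
      paste(round(encode_hp(h, space), 8), collapse = ","), character(1))
    keep <- !duplicated(keys) & !(keys %in% seen)
    list(pool = pool[keep], keys = keys[keep])
  }
  # warm-up: unique random draws
  k <- 0L
  while (length(hps) < n_initial) {
    k <- k + 1L
    if (k > length(seeds)) break
    cand <- propose_unseen(seeds[k], 32L)
    if (length(cand$pool) == 0L) break
    hp <- cand$pool[[1]]
    seen <- c(seen, cand$keys[1])
    hps[[length(hps) + 1L]] <- hp
    enc <- rbind(enc, encode_hp(hp, space))
    objs <- c(objs, run_trial(objective, hp))
  }
  # surrogate-guided trials
  while (length(hps) < n_trials) {
    s <- seeds[n_trials + length(hps) + 1L]
    cand <- propose_unseen(s, n_candidates)
    if (length(cand$pool) == 0L) break  # space exhausted
    ok <- is.finite(objs)
    pick <- if (sum(ok) >= 2L) {
      fit <- gp_fit(enc[ok, , drop = FALSE], objs[ok])
      Xc <- do.call(rbind, lapply(cand$pool, encode_hp, space = space))
      pr <- gp_predict(fit, Xc)
      which.max(expected_improvement(pr$mean, pr$sd, min(objs[ok])))
    } else 1L
    hp <- cand$pool[[pick]]
    seen <- c(seen, cand$keys[pick])
    hps[[length(hps) + 1L]] <- hp
    enc <- rbind(enc, encode_hp(hp, space))
    objs <- c(objs, run_trial(objective, hp))
  }
  trials <- tibble(trial = seq_along(hps), objective = objs, hp = hps)
  new_hpo_result(trials, space, "bayes", seed)
}

#' Tune one architecture on training data
#'
#' Runs hyperparameter search where the objective is the validation RMSE
#' (original units, mmol/L) of a model trained with the sampled
#' configuration. The validation set is the chronologically last 25% of
#' the supplied training samples; the scaler is refitted on the remaining
#' sub-training block for every trial, so no validation value ever leaks
#' into preprocessing.
#'
#' @param train_ds a `supervised_ds` of training samples in original units.
#' @param model_kind architecture to tune.
#' @param n_trials,n_initial search budget (see [bayes_optimize()]).
#' @param epochs,batch_size training settings per trial (defaults 20 and 1).
#' @param seed integer seed driving sampling and every trial's training.
#' @param space optional [search_space()] override.
#' @param method `"bayes"` (default) or `"random"`.
#' @return An `hpo_result`.
#' @export
select_architecture <- function(train_ds, model_kind, n_trials = 20,
                                n_initial = 5, epochs = 20, batch_size = 1,
                                seed = 1L, space = NULL,
                                method = c("bayes", "random")) {
  stopifnot(inherits(train_ds, "supervised_ds"))
  method <- match.arg(method)
  if (train_ds$scaled) {
    abort("`train_ds` must be in original units; scaling happens per trial.",
          class = "glucast_scale_error")
  }
  if (is.null(space)) space <- search_space(model_kind, lag = train_ds$lag)
  parts <- chronological_split(train_ds, 0.75)
  scaler <- fit_scaler(parts$train)
  sub_train <- apply_scaler(parts$train, scaler)
  val <- apply_scaler(parts$test, scaler)
  trial_seeds <- derive_seeds(seed + 1L, n_trials + 8L)
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  objective <- function(hp) {
    counter$i <- counter$i + 1L
    fit <- fit_forecaster(build_model(hp), sub_train, epochs = epochs,
                          batch_size = batch_size,
                          seed = trial_seeds[min(counter$i, length(trial_seeds))])
    pred <- predict(fit, val$X)
    rmse(invert_scaler(val$y, scaler), pred)
  }
  if (method == "bayes") {
    bayes_optimize(objective, space, n_trials = n_trials,
                   n_initial = min(n_initial, n_trials), seed = seed)
  } else {
    random_search(objective, space, n_trials = n_trials, seed = seed)
  }
}

#' Serialise a search result to JSON
#'
#' @param x an `hpo_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hpo_json <- function(x, path) {
  stopifnot(inherits(x, "hpo_result"))
  strip <- function(hp) hp[!vapply(hp, is.null, logical(1))]
  out <- list(method = x$method, seed = x$seed,
              best = list(objective = x$best$objective,
                          trial = x$best$trial,
                          hyper_params = strip(unclass(x$best$hyper_params))),
              trials = lapply(seq_len(nrow(x$trials)), function(i) {
                list(trial = x$trials$trial[i],
                     objective = x$trials$objective[i],
                     hyper_params = strip(unclass(x$trials$hp[[i]])))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
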