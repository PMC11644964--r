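# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one top-level seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "glucast_param_error")
  }
  lo_bad <- if (strict_min) x <= min else x < min
  hi_bad <- if (strict_max) x >= max else x > max
  if (lo_bad || hi_bad) {
    abort(sprintf("`%s` = %s is outside its valid range.", name, format(x)),
          class = "glucast_param_error")
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "glucast_param_error")
  }
  invisible(x)
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
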