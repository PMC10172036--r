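# internal helpers

# Run code with a temporary RNG state seeded by `seed`; global state restored.
with_seed <- function(seed, code) {
  seed <- check_seed(seed)
  withr::with_seed(seed, code)
}

check_seed <- function(seed) {
  if (length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite integer.")
  }
  as.integer(seed %% 2147483647)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside %s%g, %g%s.", name, x,
      if (lower_open) "(" else "[", lower, upper,
      if (upper_open) ")" else "]"
    ))
  }
  x
}

check_count <- function(x, name, lower = 1) {
  check_scalar(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be an integer.", name))
  as.integer(x)
}

# Column standardization with population (1/n) variance, matching the
# convention used throughout (so that crossprod(X)/n is exactly the sample
# correlation matrix). Returns the scaled matrix and the kept-column mask.
standardize_columns <- function(m, drop_zero_var = TRUE, tol = 1e-12) {
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu, `-`)
  v <- colMeans(m * m)
  keep <- v > tol
  if (drop_zero_var && !all(keep)) {
    m <- m[, keep, drop = FALSE]
    v <- v[keep]
  } else if (!all(keep)) {
    v[!keep] <- 1 # leave zero columns at zero
  }
  m <- sweep(m, 2L, sqrt(v), `/`)
  list(x = m, keep = keep)
}

standardize_vector <- function(y) {
  y <- y - mean(y)
  v <- mean(y * y)
  if (v <= 1e-12) abort("vector has zero variance; cannot standardize.")
  y / sqrt(v)
}
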