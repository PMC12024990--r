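# internal argument checking helpers

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (strict_lower && x <= lower)
    abort(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  if (!strict_lower && x < lower)
    abort(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  if (x > upper)
    abort(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  invisible(x)
}

assert_fraction <- function(x, name) {
  assert_scalar_num(x, name)
  if (x <= 0 || x > 1)
    abort(sprintf("`%s` must lie in (0, 1] (got %g).", name, x))
  invisible(x)
}

# deterministic 32-bit sub-seed derivation, kept well inside .Machine$integer.max
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483587) + 1L
}

vec3 <- function(x, name) {
  if (length(x) == 1L) x <- rep(x, 3)
  if (length(x) != 3L || !is.numeric(x))
    abort(sprintf("`%s` must be a numeric vector of length 1 or 3.", name))
  as.numeric(x)
}
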