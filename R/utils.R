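# Internal helpers shared across the package.

# Classed error so callers and tests can condition on failure mode rather
# than on message wording.
bqr_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "bqridge_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Relative tolerance under which an eigenvalue of X'X is treated as zero.
.lambda_tol <- 1e-10

# Guard for coefficients entering a squared reciprocal.
.alpha_tol <- 1e-12

# Deterministic per-replication seed stream. Kept strictly below 2^31 so it
# is always a valid integer seed; the multiplier is the classic Lehmer one.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 10007) %% 2147483629)
}

assert_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    bqr_stop("bqridge_config_error", sprintf("'%s' must be a finite numeric scalar", name))
  if (x < lower)
    bqr_stop("bqridge_domain_error", sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  invisible(x)
}
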