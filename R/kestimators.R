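# The five classical scalar rules for the ridge biasing parameter, plus the
# per-coordinate rule they are all summaries of. Each takes the canonical
# OLS coefficients and the residual variance estimate; HSL additionally
# weights by the eigenvalues. All are sign-invariant in alpha (only squares
# enter) and scale linearly in sigma2.

.check_alpha_sigma <- function(alpha, sigma2) {
  if (!is.numeric(alpha) || length(alpha) < 1L || any(!is.finite(alpha)))
    bqr_stop("bqridge_invalid_data", "'alpha' must be a finite numeric vector")
  assert_scalar_number(sigma2, "sigma2", lower = 0)
}

#' Per-coordinate ridge parameters
#'
#' The coordinate-wise rule `k_w = sigma2 / alpha_w^2`, the quantity whose
#' minimum, harmonic, geometric and arithmetic means define the scalar
#' rules below.
#'
#' @param alpha Canonical OLS coefficients (all nonzero).
#' @param sigma2 Residual variance estimate (>= 0).
#' @return Numeric vector of length `p`.
#' @export
k_per_coordinate <- function(alpha, sigma2) {
  .check_alpha_sigma(alpha, sigma2)
  if (any(abs(alpha) < .alpha_tol))
    bqr_stop("bqridge_degenerate",
             "per-coordinate rule undefined: some alpha_w is (numerically) zero")
  sigma2 / alpha^2
}

#' Hoerl--Kennard rule
#'
#' `k_HK = sigma2 / max(alpha_w^2)`: the single value obtained by replacing
#' every coordinate by the largest-magnitude coefficient. Equals the minimum
#' of the per-coordinate rule.
#'
#' @inheritParams k_per_coordinate
#' @return Named scalar (`"HK"`).
#' @export
k_hk <- function(alpha, sigma2) {
  .check_alpha_sigma(alpha, sigma2)
  a2 <- max(alpha^2)
  if (a2 < .alpha_tol^2)
    bqr_stop("bqridge_degenerate", "HK rule undefined: all coefficients are zero")
  c(HK = sigma2 / a2)
}

#' Hoerl--Kennard--Baldwin rule
#'
#' `k_HKB = p * sigma2 / sum(alpha_w^2)`, the harmonic mean of the
#' per-coordinate rule.
#'
#' @inheritParams k_per_coordinate
#' @return Named scalar (`"HKB"`).
#' @export
k_hkb <- function(alpha, sigma2) {
  .check_alpha_sigma(alpha, sigma2)
  s <- sum(alpha^2)
  if (s < .alpha_tol^2)
    bqr_stop("bqridge_degenerate", "HKB rule undefined: sum(alpha^2) is zero")
  c(HKB = length(alpha) * sigma2 / s)
}

#' Hocking--Speed--Lynn rule
#'
#' Eigenvalue-weighted rule
#' `k_HSL = sigma2 * sum((lambda_w alpha_w)^2) / (sum(lambda_w alpha_w^2))^2`.
#' For `p = 1` it reduces to `sigma2 / alpha_1^2` independently of the
#' eigenvalue.
#'
#' @inheritParams k_per_coordinate
#' @param lambdas Eigenvalues of `X'X`, same length as `alpha`.
#' @return Named scalar (`"HSL"`).
#' @export
k_hsl <- function(alpha, lambdas, sigma2) {
  .check_alpha_sigma(alpha, sigma2)
  if (length(lambdas) != length(alpha))
    bqr_stop("bqridge_dimension_error", "lambdas and alpha lengths differ")
  den <- sum(lambdas * alpha^2)
  if (den < .alpha_tol^2)
    bqr_stop("bqridge_degenerate", "HSL rule undefined: sum(lambda * alpha^2) is zero")
  c(HSL = sigma2 * sum((lambdas * alpha)^2) / den^2)
}

#' Arithmetic-mean rule
#'
#' `k_AM = mean(sigma2 / alpha_w^2)`, the arithmetic mean of the
#' per-coordinate rule.
#'
#' @inheritParams k_per_coordinate
#' @return Named scalar (`"AM"`).
#' @export
k_am <- function(alpha, sigma2) {
  c(AM = unname(mean(k_per_coordinate(alpha, sigma2))))
}

#' Geometric-mean rule
#'
#' `k_GM = sigma2 / (prod(alpha_w^2))^{1/p}`, the geometric mean of the
#' per-coordinate rule. The product is evaluated in log space so it neither
#' underflows nor overflows at large `p`.
#'
#' @inheritParams k_per_coordinate
#' @return Named scalar (`"GM"`).
#' @export
k_gm <- function(alpha, sigma2) {
  .check_alpha_sigma(alpha, sigma2)
  if (any(abs(alpha) < .alpha_tol))
    bqr_stop("bqridge_degenerate", "GM rule undefined: some alpha_w is (numerically) zero")
  c(GM = sigma2 / exp(mean(log(alpha^2))))
}

# Vector of all five rules from precomputed components; used on every
# bootstrap resample, so kept allocation-light. Returns NULL when AM/GM are
# degenerate (caller redraws).
.k_all <- function(alpha, lambdas, sigma2) {
  a2 <- alpha * alpha
  if (min(a2) < .alpha_tol^2) return(NULL)
  c(HK  = sigma2 / max(a2),
    HKB = length(alpha) * sigma2 / sum(a2),
    HSL = sigma2 * sum((lambdas * alpha)^2) / sum(lambdas * a2)^2,
    AM  = mean(sigma2 / a2),
    GM  = sigma2 / exp(mean(log(a2))))
}

#' All five scalar ridge-parameter estimates for a dataset
#'
#' Convenience wrapper running the canonical decomposition, the OLS fit and
#' the residual variance estimate, then evaluating all five rules.
#'
#' @param data A [ridge_data()] object.
#' @return Named numeric vector `c(HK, HKB, HSL, AM, GM)`, with the
#'   components used attached as attributes `sigma2` and `lambdas`.
#' @examples
#' set.seed(1)
#' X <- generate_design(30, 4, 0.9)
#' d <- ridge_data(X, X %*% c(1, 0, 0, 0) + rnorm(30))
#' k_estimate_all(d)
#' @export
k_estimate_all <- function(data) {
  if (!inherits(data, "ridge_data")) data <- ridge_data(data$X, data$y)
  fc <- .fit_components(data$X, data$y)
  if (is.null(fc))
    bqr_stop("bqridge_singular", "X'X numerically singular; no OLS-based k rules")
  ks <- tryCatch(.k_all(fc$alpha, fc$lambdas, fc$sigma2), error = identity)
  if (is.null(ks))
    bqr_stop("bqridge_degenerate",
             "AM/GM rules undefined: some canonical OLS coefficient is zero")
  structure(ks, sigma2 = fc$sigma2, lambdas = fc$lambdas)
}
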