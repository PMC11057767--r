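#' Bundle a design matrix and response for ridge estimation
#'
#' Validates and packages an `n x p` design matrix with its length-`n`
#' response. The model is `y = X beta + e` with no intercept: the methods in
#' this package assume the intercept is zero (real-data workflows achieve
#' this by centring, see [load_regression_csv()]).
#'
#' @param X Numeric matrix with `n` rows and `p` columns, `n > p >= 1`.
#' @param y Numeric response vector of length `n`.
#' @return An object of class `"ridge_data"`: a list with components `X`,
#'   `y`, `n`, `p`.
#' @examples
#' d <- ridge_data(matrix(rnorm(30), 10, 3), rnorm(10))
#' d$n; d$p
#' @export
ridge_data <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X) || !is.numeric(y))
    bqr_stop("bqridge_invalid_data", "'X' and 'y' must be numeric")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n)
    bqr_stop("bqridge_dimension_error",
             sprintf("length(y) == %d but nrow(X) == %d", length(y), n))
  if (!(n > p && p >= 1L))
    bqr_stop("bqridge_invalid_data",
             sprintf("need n > p >= 1 (got n = %d, p = %d)", n, p))
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y)))
    bqr_stop("bqridge_invalid_data", "non-finite entries in X or y")
  structure(list(X = X, y = y, n = n, p = p), class = "ridge_data")
}

#' @export
print.ridge_data <- function(x, ...) {
  cat(sprintf("<ridge_data: n = %d, p = %d>\n", x$n, x$p))
  invisible(x)
}

#' Canonical decomposition of the cross-product matrix
#'
#' Computes the eigendecomposition `X'X = U diag(lambda) U'` and the rotated
#' design `Z = X U`, so that `Z'Z = diag(lambda)` and the ridge problem
#' separates coordinate-wise. Eigenvalues are returned in descending order.
#' The sign of each eigenvector column is fixed so that its largest-magnitude
#' entry is positive, which makes the decomposition deterministic across
#' platforms and repeated calls.
#'
#' @param data A [ridge_data()] object, or a bare numeric matrix.
#' @return An object of class `"canonical_decomposition"`: list with `U`
#'   (p x p orthogonal), `lambdas` (descending, length p), `Z` (n x p),
#'   `n`, `p`.
#' @examples
#' d <- ridge_data(matrix(rnorm(30), 10, 3), rnorm(10))
#' dec <- canonical_decompose(d)
#' max(abs(crossprod(dec$Z) - diag(dec$lambdas)))  # ~ 0
#' @export
canonical_decompose <- function(data) {
  X <- if (inherits(data, "ridge_data")) data$X else as.matrix(data)
  if (anyNA(X) || !all(is.finite(X)))
    bqr_stop("bqridge_invalid_data", "non-finite entries in X")
  p <- ncol(X)
  eg <- eigen(crossprod(X), symmetric = TRUE)
  lam <- pmax(eg$values, 0)  # clip tiny negative round-off
  U <- eg$vectors
  for (j in seq_len(p)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(U = U, lambdas = lam, Z = X %*% U, n = nrow(X), p = p),
            class = "canonical_decomposition")
}

#' @export
print.canonical_decomposition <- function(x, ...) {
  cat(sprintf("<canonical_decomposition: p = %d, lambda range [%.4g, %.4g]>\n",
              x$p, min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

.check_decomp <- function(decomp) {
  if (!inherits(decomp, "canonical_decomposition"))
    bqr_stop("bqridge_invalid_data", "expected a 'canonical_decomposition' object")
  decomp
}

coef_estimate <- function(alpha, k_used, space = c("canonical", "original")) {
  structure(list(alpha = as.numeric(alpha), k_used = as.numeric(k_used),
                 space = match.arg(space)),
            class = "coef_estimate")
}

#' @export
print.coef_estimate <- function(x, ...) {
  cat(sprintf("<coef_estimate (%s space), k in [%.4g, %.4g]>\n",
              x$space, min(x$k_used), max(x$k_used)))
  print(x$alpha)
  invisible(x)
}

#' Ordinary least squares in canonical coordinates
#'
#' `alpha_hat = Lambda^{-1} Z'y`, equivalent to the usual normal-equations
#' solution rotated by `U'`. Requires all eigenvalues to be bounded away
#' from zero.
#'
#' @param decomp A [canonical_decompose()] result.
#' @param y Numeric response of length `n`.
#' @return A `"coef_estimate"` in canonical space with `k_used = 0`.
#' @export
ols_alpha <- function(decomp, y) {
  .check_decomp(decomp)
  lam <- decomp$lambdas
  bad <- which(lam <= .lambda_tol * max(lam))
  if (length(bad))
    bqr_stop("bqridge_singular",
             sprintf("X'X numerically singular: eigenvalue index %s below tolerance",
                     paste(bad, collapse = ", ")))
  zy <- crossprod(decomp$Z, y)[, 1L]
  coef_estimate(zy / lam, rep(0, decomp$p), "canonical")
}

#' Ridge estimator in canonical coordinates
#'
#' `alpha_hat(k)_w = (Z'y)_w / (lambda_w + k_w)`. With `k = 0` this equals
#' the OLS solution; as `k` grows every coordinate shrinks monotonically
#' toward zero. `k` may be a scalar (the usual case: `K = k I`) or a vector
#' of per-coordinate parameters.
#'
#' @inheritParams ols_alpha
#' @param k Non-negative scalar or length-`p` vector of ridge parameters.
#' @return A `"coef_estimate"` in canonical space.
#' @examples
#' # lambda = (2, 1), Z'y = (4, 3), k = 1  ->  alpha = (4/3, 3/2)
#' @export
ridge_alpha <- function(decomp, y, k) {
  .check_decomp(decomp)
  p <- decomp$p
  if (!is.numeric(k) || !(length(k) %in% c(1L, p)))
    bqr_stop("bqridge_dimension_error", "'k' must be a scalar or length-p vector")
  if (any(!is.finite(k)) || any(k < 0))
    bqr_stop("bqridge_domain_error", "ridge parameter k must be finite and >= 0")
  kv <- rep_len(as.numeric(k), p)
  zy <- crossprod(decomp$Z, y)[, 1L]
  coef_estimate(zy / (decomp$lambdas + kv), kv, "canonical")
}

#' Unbiased residual variance estimate
#'
#' `sigma2_hat = sum(resid^2) / (n - p)` with residuals from the canonical
#' OLS fit, `resid = y - Z alpha_hat`. This is the usual residual mean
#' square for the no-intercept model.
#'
#' @param data A [ridge_data()] object.
#' @param alpha_ols OLS `"coef_estimate"` in canonical space (computed if
#'   missing).
#' @param decomp Matching decomposition (computed if missing).
#' @return Non-negative scalar estimate of the error variance.
#' @export
sigma2_hat <- function(data, alpha_ols = NULL, decomp = NULL) {
  if (!inherits(data, "ridge_data")) data <- ridge_data(data$X, data$y)
  if (data$n <= data$p)
    bqr_stop("bqridge_invalid_data", "need n > p for the residual mean square")
  decomp <- decomp %||% canonical_decompose(data)
  alpha_ols <- alpha_ols %||% ols_alpha(decomp, data$y)
  r <- data$y - decomp$Z %*% alpha_ols$alpha
  sum(r^2) / (data$n - data$p)
}

#' Theoretical mean squared error of the canonical ridge estimator
#'
#' Variance plus squared bias of `alpha_hat(k)` given the eigenvalues, the
#' true canonical coefficients and the true error variance:
#' `sigma2 * sum(lambda / (lambda + k)^2) + sum(k^2 alpha^2 / (lambda + k)^2)`.
#' At `k = 0` it reduces to `sigma2 * sum(1 / lambda)`, the OLS risk. The
#' coordinate-wise minimiser is `k_w = sigma2 / alpha_w^2`.
#'
#' @param lambdas Positive eigenvalues of `X'X` (length p).
#' @param k Non-negative ridge parameter, scalar or length p.
#' @param alpha_true True canonical coefficients (length p).
#' @param sigma2 True error variance (non-negative scalar).
#' @return Scalar MSE.
#' @examples
#' theoretical_mse(c(4, 1), 1, c(1, 1), 1)  # 4/25 + 1/25 + 1/4 + 1/4 = 0.70
#' @export
theoretical_mse <- function(lambdas, k, alpha_true, sigma2) {
  p <- length(lambdas)
  if (length(alpha_true) != p)
    bqr_stop("bqridge_dimension_error", "lambdas and alpha_true lengths differ")
  if (!(length(k) %in% c(1L, p)))
    bqr_stop("bqridge_dimension_error", "'k' must be a scalar or length-p vector")
  if (any(lambdas <= 0))
    bqr_stop("bqridge_domain_error", "all eigenvalues must be > 0")
  if (any(k < 0))
    bqr_stop("bqridge_domain_error", "ridge parameter k must be >= 0")
  assert_scalar_number(sigma2, "sigma2", lower = 0)
  kv <- rep_len(as.numeric(k), p)
  d <- (lambdas + kv)^2
  sigma2 * sum(lambdas / d) + sum(kv^2 * alpha_true^2 / d)
}

#' Rotate a canonical estimate back to the original predictor space
#'
#' `beta_hat = U alpha_hat`. Round-trips with `U' beta_hat` to numerical
#' tolerance since `U` is orthogonal.
#'
#' @param est A `"coef_estimate"` in canonical space.
#' @param decomp The matching [canonical_decompose()] result.
#' @return A `"coef_estimate"` with `space = "original"`.
#' @export
to_original_space <- function(est, decomp) {
  .check_decomp(decomp)
  if (!inherits(est, "coef_estimate") || est$space != "canonical")
    bqr_stop("bqridge_invalid_data", "'est' must be a canonical-space coef_estimate")
  if (length(est$alpha) != decomp$p)
    bqr_stop("bqridge_dimension_error", "coefficient length does not match decomposition")
  coef_estimate(decomp$U %*% est$alpha, est$k_used, "original")
}

# Lean fitted-components helper used by the estimator, bootstrap and
# simulation layers: one eigendecomposition, canonical OLS, and the residual
# mean square, without intermediate S3 wrappers. RSS is computed as
# y'y - sum(alpha * Z'y), exact for orthogonal Z columns.
.fit_components <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  eg <- eigen(crossprod(X), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  for (j in seq_len(p)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  if (lam[p] <= .lambda_tol * lam[1L]) return(NULL)  # caller decides
  zy <- crossprod(U, crossprod(X, y))[, 1L]
  alpha <- zy / lam
  rss <- max(sum(y * y) - sum(zy * alpha), 0)
  list(U = U, lambdas = lam, zy = zy, alpha = alpha,
       sigma2 = rss / (n - p), n = n, p = p)
}
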