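# Nonparametric pairs bootstrap of a ridge-parameter rule and selection of
# an empirical quantile of its bootstrap distribution. The selected quantile
# replaces the full-sample estimate: on collinear data the upper tail of the
# bootstrap distribution carries the larger k values whose extra shrinkage
# pays for itself in MSE.

.rule_labels <- c("HK", "HKB", "HSL", "AM", "GM")

#' Bootstrap settings
#'
#' @param B Number of bootstrap resamples (>= 2). Default 200.
#' @param seed Optional integer seed; when supplied, bootstrap draws are
#'   reproducible.
#' @param gamma_grid Strictly increasing quantile levels in (0, 1) over which
#'   a level is selected. Default `seq(0.50, 0.95, by = 0.05)`: upper
#'   quantiles, since larger-than-baseline k is where the MSE gain lies.
#' @param max_redraws Budget of extra resamples allowed to replace degenerate
#'   ones (rank-deficient resampled design, or a zero canonical coefficient
#'   that leaves AM/GM undefined). Default `10 * B`.
#' @return An object of class `"bootstrap_settings"`.
#' @export
bootstrap_settings <- function(B = 200L, seed = NULL,
                               gamma_grid = seq(0.50, 0.95, by = 0.05),
                               max_redraws = 10L * B) {
  B <- as.integer(B)
  if (is.na(B) || B < 2L)
    bqr_stop("bqridge_config_error", "'B' must be an integer >= 2")
  if (length(gamma_grid) < 1L || any(!is.finite(gamma_grid)) ||
      any(gamma_grid <= 0) || any(gamma_grid >= 1) ||
      (length(gamma_grid) > 1L && any(diff(gamma_grid) <= 0)))
    bqr_stop("bqridge_config_error",
             "'gamma_grid' must be strictly increasing within (0, 1)")
  max_redraws <- as.integer(max_redraws)
  if (is.na(max_redraws) || max_redraws < 1L)
    bqr_stop("bqridge_config_error", "'max_redraws' must be a positive integer")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(B = B, seed = seed, gamma_grid = as.numeric(gamma_grid),
                 max_redraws = max_redraws),
            class = "bootstrap_settings")
}

#' Resample observation pairs with replacement
#'
#' Case (pairs) resampling: `n` rows are drawn jointly from the
#' `(X_j, y_j)` pairs, preserving the row pairing. Uses the current RNG
#' state, so wrap in `set.seed()` for reproducibility.
#'
#' @param data A [ridge_data()] object.
#' @return A new `"ridge_data"` object with the resampled rows.
#' @export
resample_pairs <- function(data) {
  if (!inherits(data, "ridge_data"))
    bqr_stop("bqridge_invalid_data", "'data' must be a ridge_data object")
  idx <- sample.int(data$n, data$n, replace = TRUE)
  structure(list(X = data$X[idx, , drop = FALSE], y = data$y[idx],
                 n = data$n, p = data$p),
            class = "ridge_data")
}

# B x m matrix of bootstrap k values; cols = requested rules. Degenerate
# resamples are replaced and counted. Inner loop shared by the public
# distribution builder and the simulation engine.
.boot_k_matrix <- function(X, y, B, max_redraws, rule_fn = NULL) {
  n <- nrow(X); p <- ncol(X)
  m <- if (is.null(rule_fn)) 5L else 1L
  out <- matrix(NA_real_, B, m)
  n_redraws <- 0L
  u <- 1L
  while (u <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    kv <- if (is.null(rule_fn)) {
      fc <- .fit_components(Xb, yb)
      if (is.null(fc)) NULL else .k_all(fc$alpha, fc$lambdas, fc$sigma2)
    } else {
      val <- tryCatch(rule_fn(structure(list(X = Xb, y = yb, n = n, p = p),
                                        class = "ridge_data")),
                      error = function(e) NULL)
      if (is.null(val) || !is.finite(val) || val < 0) NULL else as.numeric(val)
    }
    if (is.null(kv) || any(!is.finite(kv))) {
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws)
        bqr_stop("bqridge_unstable_bootstrap",
                 sprintf("redraw budget exhausted: %d degenerate resamples for %d kept (%.0f%% failure)",
                         n_redraws, u - 1L, 100 * n_redraws / (n_redraws + u - 1L)))
      next
    }
    out[u, ] <- kv
    u <- u + 1L
  }
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Bootstrap distribution of a ridge-parameter rule
#'
#' Draws `B` pairs-bootstrap resamples, evaluates the rule on each, and
#' returns the order statistics `k*(1) <= ... <= k*(B)`. Resamples on which
#' the rule is undefined (rank-deficient design, zero coefficient for
#' AM/GM) are redrawn and counted, up to `settings$max_redraws`.
#'
#' @param data A [ridge_data()] object.
#' @param rule One of `"HK"`, `"HKB"`, `"HSL"`, `"AM"`, `"GM"`, or a
#'   function `f(ridge_data) -> scalar k` for a user-supplied rule.
#' @param settings A [bootstrap_settings()] object.
#' @return An object of class `"bqr_kdist"`: list with `estimator`,
#'   sorted `values` (length B), `B`, `n_redraws`.
#' @export
bootstrap_k_distribution <- function(data, rule = "HK",
                                     settings = bootstrap_settings()) {
  if (!inherits(data, "ridge_data"))
    bqr_stop("bqridge_invalid_data", "'data' must be a ridge_data object")
  if (!inherits(settings, "bootstrap_settings"))
    bqr_stop("bqridge_config_error", "'settings' must come from bootstrap_settings()")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  if (is.character(rule)) {
    rule <- match.arg(rule, .rule_labels)
    km <- .boot_k_matrix(data$X, data$y, settings$B, settings$max_redraws)
    vals <- km[, match(rule, .rule_labels)]
    label <- rule
  } else if (is.function(rule)) {
    km <- .boot_k_matrix(data$X, data$y, settings$B, settings$max_redraws,
                         rule_fn = rule)
    vals <- km[, 1L]
    label <- "custom"
  } else {
    bqr_stop("bqridge_config_error", "'rule' must be an estimator label or a function")
  }
  structure(list(estimator = label, values = sort(vals), B = settings$B,
                 n_redraws = attr(km, "n_redraws")),
            class = "bqr_kdist")
}

#' @export
print.bqr_kdist <- function(x, ...) {
  cat(sprintf("<bootstrap k distribution: %s, B = %d, redraws = %d>\n",
              x$estimator, x$B, x$n_redraws))
  print(stats::quantile(x$values, c(0, .25, .5, .75, 1)))
  invisible(x)
}

#' Empirical quantile of a bootstrap distribution
#'
#' Returns the order statistic `k*(ceiling(gamma * B))` (inverse empirical
#' CDF, no interpolation), which satisfies the defining inequality
#' `P(k* < q) <= gamma <= P(k* <= q)` on the empirical distribution and is
#' exactly reproducible. Vectorised over `gamma`.
#'
#' @param dist A `"bqr_kdist"` object or a bare numeric vector of bootstrap
#'   replicates.
#' @param gamma Quantile level(s) in (0, 1).
#' @return Numeric of the same length as `gamma`.
#' @examples
#' empirical_quantile(c(1, 2, 3, 4, 5), 0.5)  # 3
#' empirical_quantile(c(1, 2, 3, 4, 5), 0.8)  # 4
#' @export
empirical_quantile <- function(dist, gamma) {
  vals <- if (inherits(dist, "bqr_kdist")) dist$values else sort(as.numeric(dist))
  if (length(vals) < 1L)
    bqr_stop("bqridge_config_error", "empty bootstrap distribution")
  if (any(!is.finite(gamma)) || any(gamma <= 0) || any(gamma >= 1))
    bqr_stop("bqridge_domain_error", "'gamma' must lie strictly inside (0, 1)")
  vals[ceiling(gamma * length(vals))]
}

#' Select the quantile level for a bootstrap-quantile ridge estimate
#'
#' Three explicit strategies resolve the choice of quantile level:
#' \describe{
#'   \item{`"fixed"`}{return the single supplied `gamma`.}
#'   \item{`"min_estimated_mse"`}{evaluate the theoretical MSE with plug-in
#'     quantities (canonical OLS coefficients, residual variance, realised
#'     eigenvalues) at each grid level's quantile and return the minimiser.
#'     This is the strategy usable on real data.}
#'   \item{`"oracle"`}{same search but with the true `(alpha, sigma2)`
#'     supplied through `truth`; meaningful only in simulations.}
#' }
#' Ties are broken toward the largest `gamma` (the most conservative
#' shrinkage among the tied levels).
#'
#' @param data A [ridge_data()] object (used for plug-in quantities).
#' @param dist A `"bqr_kdist"` for the chosen rule.
#' @param settings A [bootstrap_settings()] supplying the grid.
#' @param strategy `"min_estimated_mse"`, `"fixed"` or `"oracle"`.
#' @param gamma Level for `strategy = "fixed"`.
#' @param truth List with elements `alpha` (true canonical coefficients) and
#'   `sigma2`, required for `strategy = "oracle"`.
#' @return An object of class `"bqr_selection"`: list with `gamma`,
#'   `k_star`, `criterion_value`, `strategy`.
#' @export
select_gamma <- function(data, dist, settings = bootstrap_settings(),
                         strategy = c("min_estimated_mse", "fixed", "oracle"),
                         gamma = NULL, truth = NULL) {
  strategy <- match.arg(strategy)
  grid <- settings$gamma_grid
  if (length(grid) < 1L)
    bqr_stop("bqridge_config_error", "empty gamma grid")
  if (strategy == "fixed") {
    g <- gamma %||% (if (length(grid) == 1L) grid else NULL)
    if (is.null(g))
      bqr_stop("bqridge_config_error",
               "strategy = 'fixed' needs 'gamma' (or a single-level grid)")
    ks <- empirical_quantile(dist, g)
    return(structure(list(gamma = g, k_star = ks, criterion_value = NA_real_,
                          strategy = strategy), class = "bqr_selection"))
  }
  fc <- .fit_components(data$X, data$y)
  if (is.null(fc))
    bqr_stop("bqridge_singular", "X'X numerically singular; cannot evaluate the MSE criterion")
  if (strategy == "oracle") {
    if (is.null(truth) || is.null(truth$alpha) || is.null(truth$sigma2))
      bqr_stop("bqridge_config_error",
               "strategy = 'oracle' needs truth = list(alpha = ..., sigma2 = ...)")
    a <- truth$alpha; s2 <- truth$sigma2
  } else {
    a <- fc$alpha; s2 <- fc$sigma2
  }
  kv <- empirical_quantile(dist, grid)
  crit <- vapply(kv, function(k) theoretical_mse(fc$lambdas, k, a, s2), 0)
  i <- max(which(crit == min(crit)))  # ties -> largest gamma
  structure(list(gamma = grid[i], k_star = kv[i], criterion_value = crit[i],
                 strategy = strategy),
            class = "bqr_selection")
}

#' @export
print.bqr_selection <- function(x, ...) {
  cat(sprintf("<bqr_selection: gamma = %.2f, k* = %.4g, strategy = %s>\n",
              x$gamma, x$k_star, x$strategy))
  invisible(x)
}

#' Bootstrap-quantile ridge fit (end to end)
#'
#' Runs the full procedure for one rule on one dataset: pairs-bootstrap the
#' rule `B` times, pick a quantile level by the requested strategy, and fit
#' the ridge estimator at the selected `k*`. Deterministic given
#' `settings$seed`.
#'
#' @inheritParams select_gamma
#' @param rule Estimator label or rule function (see
#'   [bootstrap_k_distribution()]).
#' @return List of class `"bqr_fit"` with components `selection`
#'   (`"bqr_selection"`), `estimate` (canonical `"coef_estimate"` at `k*`),
#'   `beta` (original-space coefficients), `k_baseline` (full-sample rule
#'   value), `distribution` (`"bqr_kdist"`), `sigma2`, `lambdas`.
#' @export
bqr_fit <- function(data, rule = "HK", settings = bootstrap_settings(),
                    strategy = c("min_estimated_mse", "fixed", "oracle"),
                    gamma = NULL, truth = NULL) {
  strategy <- match.arg(strategy)
  if (!inherits(data, "ridge_data"))
    bqr_stop("bqridge_invalid_data", "'data' must be a ridge_data object")
  dist <- bootstrap_k_distribution(data, rule, settings)
  sel <- select_gamma(data, dist, settings, strategy, gamma, truth)
  decomp <- canonical_decompose(data)
  est <- ridge_alpha(decomp, data$y, sel$k_star)
  k_base <- if (is.character(rule)) {
    unname(k_estimate_all(data)[match.arg(rule, .rule_labels)])
  } else {
    as.numeric(rule(data))
  }
  fc <- .fit_components(data$X, data$y)
  structure(list(selection = sel, estimate = est,
                 beta = to_original_space(est, decomp)$alpha,
                 k_baseline = k_base, distribution = dist,
                 sigma2 = fc$sigma2, lambdas = fc$lambdas),
            class = "bqr_fit")
}
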