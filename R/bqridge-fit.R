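#' Fit a ridge regression with bootstrap-quantile parameter selection
#'
#' `bqridge()` is the main entry point for data analysis. It prepares the
#' design (by default centring the response and centring/unit-length-scaling
#' the predictors, so that no intercept is needed), computes the requested
#' classical ridge-parameter rule, pairs-bootstraps it `B` times, replaces
#' it by the empirical quantile of the bootstrap distribution selected by
#' `strategy`, and returns the ridge fit at the selected value.
#'
#' @param x A formula or a numeric design matrix.
#' @param ... Passed between methods.
#' @return An object of class `"bqridge"`; see Details.
#'
#' @details The returned object supports `print()`, `summary()` (adds
#' collinearity diagnostics), `coef()`, `predict()`, `fitted()`,
#' `residuals()` and `plot()` (bootstrap distribution of the rule with the
#' baseline and selected values marked). Coefficients are reported on the
#' preprocessing scale recorded in `object$preprocessing`; `predict()`
#' undoes the preprocessing, so predictions are on the original response
#' scale.
#' @export
bqridge <- function(x, ...) UseMethod("bqridge")

#' @rdname bqridge
#' @param formula,data Model formula (no intercept is fitted; any intercept
#'   term is handled by centring) and data frame.
#' @param rule Ridge-parameter rule: `"HK"`, `"HKB"`, `"HSL"`, `"AM"`,
#'   `"GM"`, or a function `f(ridge_data) -> k`.
#' @param B Bootstrap resamples (default 200).
#' @param strategy Quantile-level selection: `"min_estimated_mse"`
#'   (default), `"fixed"` (supply `gamma`), or `"oracle"` (supply `truth`;
#'   simulation use).
#' @param gamma Fixed quantile level when `strategy = "fixed"`.
#' @param gamma_grid Candidate levels otherwise.
#' @param seed Optional integer seed for the bootstrap.
#' @param center_y,scale_x Preprocessing: centre the response, and scale the
#'   centred predictor columns (`"unit_length"`, `"z_score"` or `"none"`).
#' @param truth Optional list(alpha, sigma2) for `strategy = "oracle"`.
#' @export
bqridge.formula <- function(x, data = environment(x), rule = "HK", B = 200L,
                            strategy = c("min_estimated_mse", "fixed", "oracle"),
                            gamma = NULL, gamma_grid = seq(0.50, 0.95, by = 0.05),
                            seed = NULL, center_y = TRUE,
                            scale_x = c("unit_length", "z_score", "none"),
                            truth = NULL, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  if ("(Intercept)" %in% colnames(X))
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  out <- bqridge.default(X, y, rule = rule, B = B, strategy = strategy,
                         gamma = gamma, gamma_grid = gamma_grid, seed = seed,
                         center_y = center_y, scale_x = scale_x,
                         truth = truth, ...)
  out$terms <- mt
  out$call <- match.call()
  out
}

#' @rdname bqridge
#' @param y Numeric response (matrix interface).
#' @export
bqridge.default <- function(x, y, rule = "HK", B = 200L,
                            strategy = c("min_estimated_mse", "fixed", "oracle"),
                            gamma = NULL, gamma_grid = seq(0.50, 0.95, by = 0.05),
                            seed = NULL, center_y = TRUE,
                            scale_x = c("unit_length", "z_score", "none"),
                            truth = NULL, ...) {
  strategy <- match.arg(strategy)
  scale_x <- match.arg(scale_x)
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  prep <- .preprocess(X, y, center_y, scale_x)
  data <- ridge_data(prep$X, prep$y)
  settings <- bootstrap_settings(B = B, seed = seed,
                                 gamma_grid = if (strategy == "fixed" && !is.null(gamma))
                                   gamma else gamma_grid)
  fit <- bqr_fit(data, rule = rule, settings = settings, strategy = strategy,
                 gamma = gamma, truth = truth)
  beta <- stats::setNames(fit$beta, colnames(X))
  fitted_proc <- as.numeric(prep$X %*% beta)
  fitted_orig <- fitted_proc + prep$y_center
  lam <- fit$lambdas
  fc <- .fit_components(prep$X, prep$y)
  est_mse <- function(k) theoretical_mse(lam, k, fc$alpha, fc$sigma2)
  structure(list(
    call = match.call(),
    rule = if (is.character(rule)) rule else "custom",
    strategy = strategy,
    selection = fit$selection,
    k = fit$selection$k_star,
    k_baseline = fit$k_baseline,
    gamma = fit$selection$gamma,
    coefficients = beta,
    alpha = fit$estimate$alpha,
    sigma2 = fc$sigma2,
    lambdas = lam,
    est_mse = est_mse(fit$selection$k_star),
    est_mse_baseline = est_mse(fit$k_baseline),
    est_mse_ols = fc$sigma2 * sum(1 / lam),
    boot = fit$distribution,
    preprocessing = prep[c("center_y", "scale_x", "y_center", "x_center", "x_scale")],
    X = prep$X, y_original = as.numeric(y),
    fitted.values = fitted_orig,
    residuals = as.numeric(y) - fitted_orig,
    n = data$n, p = data$p), class = "bqridge")
}

.preprocess <- function(X, y, center_y, scale_x) {
  y <- as.numeric(y)
  y_center <- if (center_y) mean(y) else 0
  x_center <- if (scale_x == "none") rep(0, ncol(X)) else colMeans(X)
  Xc <- sweep(X, 2L, x_center)
  x_scale <- switch(scale_x,
    none = rep(1, ncol(X)),
    unit_length = sqrt(colSums(Xc^2)),
    z_score = apply(Xc, 2L, stats::sd))
  if (any(x_scale <= 0) || any(!is.finite(x_scale)))
    bqr_stop("bqridge_invalid_data",
             sprintf("constant predictor column(s): %s",
                     paste(colnames(X)[x_scale <= 0 | !is.finite(x_scale)],
                           collapse = ", ")))
  list(X = sweep(Xc, 2L, x_scale, "/"), y = y - y_center,
       center_y = center_y, scale_x = scale_x,
       y_center = y_center, x_center = x_center, x_scale = x_scale)
}

#' @export
print.bqridge <- function(x, digits = 4, ...) {
  cat("Bootstrap-quantile ridge regression\n")
  cat(sprintf("  rule: %s   strategy: %s   B = %d\n",
              x$rule, x$strategy, x$boot$B))
  cat(sprintf("  baseline k = %.*g   selected k* = %.*g (gamma = %.2f)\n",
              digits, x$k_baseline, digits, x$k, x$gamma))
  cat(sprintf("  estimated MSE: OLS %.*g | baseline %.*g | bootstrap-quantile %.*g\n",
              digits, x$est_mse_ols, digits, x$est_mse_baseline, digits, x$est_mse))
  cat("Coefficients (preprocessed scale):\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.bqridge <- function(object, ...) {
  structure(list(fit = object,
                 condition_number = condition_number(object$X),
                 vif = vif(object$X)),
            class = "summary.bqridge")
}

#' @export
print.summary.bqridge <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\nCollinearity diagnostics: condition number = %.4g\n",
              x$condition_number))
  cat("VIF:\n"); print(round(x$vif, 2))
  cat(sprintf("Bootstrap redraws of degenerate resamples: %d\n",
              x$fit$boot$n_redraws))
  invisible(x)
}

#' @export
coef.bqridge <- function(object, space = c("original", "canonical"), ...) {
  space <- match.arg(space)
  if (space == "canonical") object$alpha else object$coefficients
}

#' @export
predict.bqridge <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- if (!is.null(object$terms) && is.data.frame(newdata)) {
    mm <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    if ("(Intercept)" %in% colnames(mm))
      mm <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
    mm
  } else as.matrix(newdata)
  pr <- object$preprocessing
  Xs <- sweep(sweep(X, 2L, pr$x_center), 2L, pr$x_scale, "/")
  as.numeric(Xs %*% object$coefficients) + pr$y_center
}

#' @export
residuals.bqridge <- function(object, ...) object$residuals

#' @export
fitted.bqridge <- function(object, ...) object$fitted.values

#' Plot the bootstrap distribution of the ridge parameter
#'
#' Histogram of the `B` bootstrap replicates of the rule, with the baseline
#' full-sample value (dashed) and the selected quantile (solid) marked.
#'
#' @param x A `"bqridge"` fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.bqridge <- function(x, ...) {
  vals <- x$boot$values
  graphics::hist(vals, breaks = "FD", main = sprintf(
    "Bootstrap distribution of k (%s, B = %d)", x$rule, x$boot$B),
    xlab = "k", ...)
  graphics::abline(v = x$k_baseline, lty = 2)
  graphics::abline(v = x$k, lwd = 2)
  graphics::legend("topright", lty = c(2, 1), lwd = c(1, 2),
                   legend = c(sprintf("baseline k = %.3g", x$k_baseline),
                              sprintf("selected k* = %.3g (gamma = %.2f)",
                                      x$k, x$gamma)),
                   bty = "n")
  invisible(x)
}
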