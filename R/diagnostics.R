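# Real-data workflow: CSV loading with preprocessing, collinearity
# diagnostics, and the tabular fit report comparing OLS, the five baseline
# rules and their bootstrap-quantile versions on one dataset.

#' Load a regression dataset from CSV
#'
#' Reads a CSV with a header row, one numeric response column and `p`
#' numeric predictor columns, with no missing values. Preprocessing
#' (applied exactly once, recorded in the result) defaults to centring the
#' response and centring + unit-length scaling the predictors, which puts
#' the cross-product matrix in correlation form and removes the need for an
#' intercept.
#'
#' @param path CSV file path.
#' @param response Name of the response column.
#' @param center_y,scale_x See [bqridge()].
#' @param name Dataset label (defaults to the file name).
#' @return Object of class `"regression_dataset"`: list with `name`, `data`
#'   (a [ridge_data()] of the preprocessed values), `column_names`,
#'   `response`, `preprocessing`.
#' @export
load_regression_csv <- function(path, response,
                                center_y = TRUE,
                                scale_x = c("unit_length", "z_score", "none"),
                                name = basename(path)) {
  scale_x <- match.arg(scale_x)
  if (!file.exists(path))
    bqr_stop("bqridge_invalid_data", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!response %in% names(df))
    bqr_stop("bqridge_invalid_data",
             sprintf("response column '%s' not in file (columns: %s)",
                     response, paste(names(df), collapse = ", ")))
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]]))
      bqr_stop("bqridge_invalid_data", sprintf("column '%s' is not numeric", cn))
    if (anyNA(df[[cn]]))
      bqr_stop("bqridge_invalid_data",
               sprintf("missing value at row %d, column '%s'",
                       which(is.na(df[[cn]]))[1L], cn))
  }
  y <- df[[response]]
  Xdf <- df[setdiff(names(df), response)]
  X <- as.matrix(Xdf)
  prep <- .preprocess(X, y, center_y, scale_x)
  structure(list(name = name,
                 data = ridge_data(prep$X, prep$y),
                 column_names = colnames(X), response = response,
                 preprocessing = prep[c("center_y", "scale_x", "y_center",
                                        "x_center", "x_scale")]),
            class = "regression_dataset")
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("<regression_dataset '%s': n = %d, p = %d, response = %s, scaling = %s>\n",
              x$name, x$data$n, x$data$p, x$response, x$preprocessing$scale_x))
  invisible(x)
}

#' Condition number of the cross-product matrix
#'
#' `lambda_max / lambda_min` of `X'X`. Values much above ~1000 conventionally
#' indicate severe ill-conditioning.
#'
#' @param X Numeric design matrix with `p >= 2` columns.
#' @return Scalar condition number.
#' @export
condition_number <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L)
    bqr_stop("bqridge_invalid_data", "condition number needs p >= 2")
  lam <- eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values
  if (lam[length(lam)] <= .lambda_tol * lam[1L])
    bqr_stop("bqridge_singular", "X'X numerically singular; condition number unbounded")
  lam[1L] / lam[length(lam)]
}

#' Variance inflation factors
#'
#' `VIF_w = 1 / (1 - R^2_w)` where `R^2_w` comes from regressing column `w`
#' on all other columns (with intercept). A perfectly collinear column gets
#' `Inf` rather than an error. Values above 10 conventionally flag severe
#' collinearity.
#'
#' @param X Numeric design matrix with `p >= 2` columns.
#' @return Named numeric vector of length `p`.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) bqr_stop("bqridge_invalid_data", "VIF needs p >= 2")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  out <- stats::setNames(numeric(p), colnames(X))
  for (w in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -w, drop = FALSE]), X[, w])
    r <- fit$residuals
    tss <- sum((X[, w] - mean(X[, w]))^2)
    r2 <- if (tss <= 0) 1 else 1 - sum(r^2) / tss
    out[w] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Fit report comparing all estimators on one dataset
#'
#' For OLS, each baseline rule and each bootstrap-quantile version
#' (`strategy = "min_estimated_mse"`): the ridge parameter, the estimated
#' MSE (theoretical formula with plug-in OLS quantities, the only criterion
#' available when the truth is unknown) and the coefficient vector on the
#' dataset's preprocessing scale. The bootstrap-quantile candidate set is
#' the quantile grid plus the baseline value itself, so each
#' bootstrap-quantile row's estimated MSE is never above its baseline's;
#' when the baseline wins, `gamma` is recorded as `NA`.
#'
#' @param dataset A [load_regression_csv()] result (or any
#'   `"regression_dataset"`).
#' @param settings A [bootstrap_settings()]; set its `seed` for a
#'   reproducible report.
#' @return A `data.frame` of class `"bqr_fit_report"`, one row per
#'   estimator (11 rows), with attribute `"best"` naming the smallest-MSE
#'   row.
#' @export
fit_report <- function(dataset, settings = bootstrap_settings()) {
  if (!inherits(dataset, "regression_dataset"))
    bqr_stop("bqridge_invalid_data", "'dataset' must be a regression_dataset")
  data <- dataset$data
  fc <- .fit_components(data$X, data$y)
  if (is.null(fc))
    bqr_stop("bqridge_singular", "X'X numerically singular")
  lam <- fc$lambdas
  est_mse <- function(k) theoretical_mse(lam, k, fc$alpha, fc$sigma2)
  beta_at <- function(k) as.numeric(fc$U %*% (fc$zy / (lam + k)))
  ks <- k_estimate_all(data)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  km <- .boot_k_matrix(data$X, data$y, settings$B, settings$max_redraws)
  rows <- list()
  add_row <- function(estimator, variant, k, gamma) {
    b <- beta_at(k)
    names(b) <- dataset$column_names
    rows[[length(rows) + 1L]] <<- data.frame(
      estimator = estimator, variant = variant, k = k, gamma = gamma,
      est_mse = est_mse(k), t(b), check.names = FALSE, row.names = NULL)
  }
  add_row("OLS", "ols", 0, NA_real_)
  grid <- settings$gamma_grid
  for (j in seq_along(.rule_labels)) {
    rl <- .rule_labels[j]
    k_base <- unname(ks[rl])
    add_row(rl, "baseline", k_base, NA_real_)
    kv <- sort(km[, j])[ceiling(grid * settings$B)]
    cand_k <- c(kv, k_base)
    cand_g <- c(grid, NA_real_)
    crit <- vapply(cand_k, est_mse, 0)
    i <- max(which(crit == min(crit)))
    add_row(paste0("BQR_", rl), "bqr", cand_k[i], cand_g[i])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bqr_fit_report", "data.frame")
  attr(out, "best") <- out$estimator[which.min(out$est_mse)]
  attr(out, "n_redraws") <- attr(km, "n_redraws")
  attr(out, "scale") <- dataset$preprocessing$scale_x
  out
}

#' @export
print.bqr_fit_report <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$k <- sprintf("%.2f", shown$k)  # 2-decimal display; full precision kept
  shown$gamma <- ifelse(is.na(shown$gamma), "", sprintf("%.2f", shown$gamma))
  num <- vapply(shown, is.numeric, TRUE)
  shown[num] <- lapply(shown[num], function(z) round(z, 4))
  best <- attr(x, "best")
  shown$estimator <- ifelse(shown$estimator == best,
                            paste0(shown$estimator, " *"), shown$estimator)
  cat(sprintf("Fit report (coefficients on %s scale; * = smallest estimated MSE)\n",
              attr(x, "scale") %||% "preprocessed"))
  print(shown, row.names = FALSE)
  invisible(x)
}
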