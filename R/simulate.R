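# Monte Carlo engine: collinear Gaussian designs, three error laws, and the
# empirical-MSE comparison of the five baseline rules against their
# bootstrap-quantile versions. Doubles as the synthetic-data generator used
# throughout the test suite.

#' Generate a collinear Gaussian design matrix
#'
#' Columns are built from iid standard normals as
#' `x_jw = sqrt(1 - rho^2) z_jw + rho z_extra`, sharing one extra latent
#' column (`latent = "shared_extra"`, the default, the construction of
#' McDonald & Galarneau 1975 and Kibria 2003). Every pair of columns then
#' has correlation `rho^2` and each column has unit variance.
#'
#' `latent = "self_referential"` instead reuses the last design column as
#' the shared component: `x_jw = sqrt(1 - rho^2) z_jw + rho z_jp`, so column
#' `p` equals `(sqrt(1 - rho^2) + rho) z_jp`; pairwise correlations are then
#' `rho^2` among the first `p - 1` columns and `rho` against the last. This
#' variant appears in print in parts of the applied literature and is
#' provided for comparison.
#'
#' Uses the current RNG state.
#'
#' @param n Rows. @param p Columns. @param rho Collinearity parameter in
#'   `[0, 1)`.
#' @param latent `"shared_extra"` (default) or `"self_referential"`.
#' @return `n x p` numeric matrix.
#' @export
generate_design <- function(n, p, rho, latent = c("shared_extra", "self_referential")) {
  latent <- match.arg(latent)
  assert_scalar_number(rho, "rho", lower = 0)
  if (rho >= 1) bqr_stop("bqridge_domain_error", "'rho' must be < 1")
  if (latent == "shared_extra") {
    Z <- matrix(stats::rnorm(n * (p + 1L)), n, p + 1L)
    sqrt(1 - rho^2) * Z[, seq_len(p), drop = FALSE] + rho * Z[, p + 1L]
  } else {
    Z <- matrix(stats::rnorm(n * p), n, p)
    sqrt(1 - rho^2) * Z + rho * Z[, p]
  }
}

#' True coefficients for a simulated design
#'
#' Follows the standard convention of the ridge simulation literature: the
#' true `beta` is the unit-norm eigenvector of `X'X` belonging to the
#' largest eigenvalue (sign-normalised as in [canonical_decompose()]), so
#' that `beta'beta = 1` and the signal sits entirely in the best-conditioned
#' canonical coordinate: `alpha = U'beta = (1, 0, ..., 0)`.
#'
#' @param X Design matrix (full column rank).
#' @return Object of class `"true_model"`: list with `beta`, `alpha`,
#'   `lambdas`, `U`.
#' @export
generate_true_coefficients <- function(X) {
  dec <- canonical_decompose(X)
  if (dec$lambdas[dec$p] <= .lambda_tol * dec$lambdas[1L])
    bqr_stop("bqridge_singular", "design is numerically rank deficient")
  beta <- dec$U[, 1L]
  structure(list(beta = beta,
                 alpha = as.numeric(crossprod(dec$U, beta)),
                 lambdas = dec$lambdas, U = dec$U),
            class = "true_model")
}

#' Generate simulation errors
#'
#' `error_dist = "normal"` draws `N(0, sigma2)`. `"t2"` draws a raw
#' t-distribution with 2 degrees of freedom: its variance is infinite, so no
#' variance standardisation exists and `sigma2` is ignored (unit scale).
#' `"f4_16"` draws `F(4, 16)` standardised analytically to mean 0 and
#' variance 1 (mean `16/14`, variance `2*16^2*18 / (4*14^2*12)`); `sigma2`
#' is likewise ignored. Uses the current RNG state.
#'
#' @param n Number of draws. @param sigma2 Error variance (normal case).
#' @param error_dist `"normal"`, `"t2"` or `"f4_16"`.
#' @return Numeric vector of length `n`.
#' @export
generate_errors <- function(n, sigma2 = 1, error_dist = c("normal", "t2", "f4_16")) {
  if (!is.character(error_dist))
    bqr_stop("bqridge_config_error", "'error_dist' must be a character label")
  error_dist <- tryCatch(match.arg(error_dist),
                         error = function(e)
                           bqr_stop("bqridge_config_error",
                                    sprintf("unknown error distribution '%s'", error_dist[1L])))
  switch(error_dist,
    normal = {
      assert_scalar_number(sigma2, "sigma2", lower = 0)
      stats::rnorm(n, 0, sqrt(sigma2))
    },
    t2 = stats::rt(n, df = 2),
    f4_16 = {
      d1 <- 4; d2 <- 16
      mu <- d2 / (d2 - 2)
      v <- 2 * d2^2 * (d1 + d2 - 2) / (d1 * (d2 - 2)^2 * (d2 - 4))
      (stats::rf(n, d1, d2) - mu) / sqrt(v)
    })
}

#' Empirical mean squared error over Monte Carlo replications
#'
#' `(1/M) * sum_v sum_w (est_vw - truth_vw)^2`: per-replication squared
#' errors summed over coordinates, averaged over replications.
#'
#' @param estimates `M x p` matrix of estimated canonical coefficients.
#' @param truth `M x p` matrix (or length-`p` vector, recycled) of true
#'   values.
#' @return Scalar empirical MSE.
#' @export
empirical_mse <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  if (is.null(dim(truth)))
    truth <- matrix(truth, nrow(estimates), length(truth), byrow = TRUE)
  if (!all(dim(estimates) == dim(truth)))
    bqr_stop("bqridge_dimension_error", "estimate and truth dimensions differ")
  mean(rowSums((estimates - truth)^2))
}

#' Percentage MSE reduction of a bootstrap-quantile estimator
#'
#' `100 * (mse_baseline - mse_bqr) / mse_baseline`. Positive values mean the
#' bootstrap-quantile version improved on its baseline; `-100` means it
#' doubled the MSE.
#'
#' @param mse_baseline Baseline empirical MSE (> 0).
#' @param mse_bqr Bootstrap-quantile empirical MSE.
#' @return Percentage (scalar).
#' @examples
#' p_mse(0.899, 0.116)  # 87.1
#' @export
p_mse <- function(mse_baseline, mse_bqr) {
  assert_scalar_number(mse_bqr, "mse_bqr")
  if (!is.numeric(mse_baseline) || length(mse_baseline) != 1L ||
      !is.finite(mse_baseline) || mse_baseline <= 0)
    bqr_stop("bqridge_domain_error", "'mse_baseline' must be > 0")
  100 * (mse_baseline - mse_bqr) / mse_baseline
}

#' Simulation scenario configuration
#'
#' @param n Sample size. @param p Number of predictors (`n > p`).
#' @param rho Collinearity parameter in `[0, 1)`.
#' @param sigma2 Error variance (> 0; ignored by the non-normal error laws,
#'   see [generate_errors()]).
#' @param error_dist `"normal"`, `"t2"` or `"f4_16"`.
#' @param M Monte Carlo replications. Default 1000.
#' @param B Bootstrap resamples per replication. Default 200.
#' @param gamma_grid Quantile-level grid (see [bootstrap_settings()]).
#' @param strategy Quantile-selection strategy per replication: `"oracle"`
#'   (default for simulation tables), `"min_estimated_mse"`, or `"fixed"`.
#' @param gamma Level for `strategy = "fixed"`.
#' @param seed Integer base seed; every replication derives its own stream
#'   from it, so results do not depend on execution order.
#' @param latent Design construction, see [generate_design()].
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(n, p, rho, sigma2 = 1,
                            error_dist = c("normal", "t2", "f4_16"),
                            M = 1000L, B = 200L,
                            gamma_grid = seq(0.50, 0.95, by = 0.05),
                            strategy = c("oracle", "min_estimated_mse", "fixed"),
                            gamma = NULL, seed = 1L,
                            latent = c("shared_extra", "self_referential")) {
  error_dist <- match.arg(error_dist)
  strategy <- match.arg(strategy)
  latent <- match.arg(latent)
  n <- as.integer(n); p <- as.integer(p); M <- as.integer(M)
  if (!(n > p && p >= 1L))
    bqr_stop("bqridge_config_error", sprintf("need n > p >= 1 (got n = %d, p = %d)", n, p))
  assert_scalar_number(rho, "rho", lower = 0)
  if (rho >= 1) bqr_stop("bqridge_config_error", "'rho' must be < 1")
  assert_scalar_number(sigma2, "sigma2", lower = 0)
  if (sigma2 <= 0) bqr_stop("bqridge_config_error", "'sigma2' must be > 0")
  if (M < 1L) bqr_stop("bqridge_config_error", "'M' must be >= 1")
  if (strategy == "fixed" && is.null(gamma))
    bqr_stop("bqridge_config_error", "strategy = 'fixed' needs 'gamma'")
  structure(list(n = n, p = p, rho = rho, sigma2 = sigma2,
                 error_dist = error_dist, M = M,
                 bootstrap = bootstrap_settings(B = B, gamma_grid = gamma_grid),
                 strategy = strategy, gamma = gamma,
                 seed = as.integer(seed), latent = latent),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario: n = %d, p = %d, rho = %.2f, sigma2 = %g, %s errors, M = %d, B = %d, %s>\n",
              x$n, x$p, x$rho, x$sigma2, x$error_dist, x$M, x$bootstrap$B, x$strategy))
  invisible(x)
}

.estimator_labels <- c("OLS", .rule_labels, paste0("BQR_", .rule_labels))

#' Run one Monte Carlo scenario
#'
#' For each of `M` replications: draw a fresh design and true coefficient
#' vector, simulate the response, compute the canonical OLS fit and the five
#' baseline ridge fits, and (unless `bqr = FALSE`) their bootstrap-quantile
#' versions. The same `B` bootstrap resamples are shared by the five rules
#' within a replication, which removes between-rule resampling noise from
#' the comparison. Aggregates the empirical MSE per estimator, its Monte
#' Carlo standard error, and the percentage reduction of each
#' bootstrap-quantile version over its baseline.
#'
#' Fully reproducible from `config$seed`; each replication uses a derived
#' seed, so results are invariant to execution order.
#'
#' @param config A [scenario_config()].
#' @param bqr If `FALSE`, skip the bootstrap layer (baselines and OLS only).
#' @return Object of class `"scenario_result"`: list with named `mse`,
#'   `mc_se`, `p_mse`, `mean_gamma`, `n_redraws`, `config`.
#' @export
run_scenario <- function(config, bqr = TRUE) {
  if (!inherits(config, "scenario_config"))
    bqr_stop("bqridge_config_error", "'config' must come from scenario_config()")
  n <- config$n; p <- config$p; rho <- config$rho; s2 <- config$sigma2
  M <- config$M; B <- config$bootstrap$B
  grid <- config$bootstrap$gamma_grid
  labels <- if (bqr) .estimator_labels else .estimator_labels[1:6]
  sq <- matrix(NA_real_, M, length(labels), dimnames = list(NULL, labels))
  gsel <- if (bqr) matrix(NA_real_, M, 5L) else NULL
  redraws <- 0L
  alpha_true <- c(1, rep(0, p - 1L))
  for (v in seq_len(M)) {
    set.seed(derive_seed(config$seed, v))
    fc <- NULL
    for (attempt in 1:100) {  # redraw rank-deficient designs (essentially never)
      X <- generate_design(n, p, rho, config$latent)
      dec <- eigen(crossprod(X), symmetric = TRUE)
      if (dec$values[p] > .lambda_tol * dec$values[1L]) break
      X <- NULL
    }
    if (is.null(X))
      bqr_stop("bqridge_singular",
               sprintf("replication %d: could not draw a full-rank design", v))
    lam <- dec$values
    U <- dec$vectors
    i1 <- which.max(abs(U[, 1L])); if (U[i1, 1L] < 0) U[, 1L] <- -U[, 1L]
    beta <- U[, 1L]
    y <- as.numeric(X %*% beta) + generate_errors(n, s2, config$error_dist)
    zy <- crossprod(U, crossprod(X, y))[, 1L]
    a_ols <- zy / lam
    rss <- max(sum(y * y) - sum(zy * a_ols), 0)
    sg2 <- rss / (n - p)
    err0 <- a_ols - alpha_true
    sq[v, "OLS"] <- sum(err0 * err0)
    ks <- .k_all(a_ols, lam, sg2)
    if (is.null(ks)) { # zero coefficient on the full sample: keep OLS row only
      next
    }
    for (j in 1:5) {
      e <- zy / (lam + ks[j]) - alpha_true
      sq[v, 1L + j] <- sum(e * e)
    }
    if (!bqr) next
    km <- .boot_k_matrix(X, y, B, config$bootstrap$max_redraws)
    redraws <- redraws + attr(km, "n_redraws")
    for (j in 1:5) {
      kv <- sort(km[, j])[ceiling(grid * B)]
      crit <- switch(config$strategy,
        oracle = {
          # alpha_true = e1, so the bias term involves lambda_1 only
          d2 <- outer(lam, kv, `+`)^2
          s2 * colSums(lam / d2) + kv^2 / (lam[1L] + kv)^2
        },
        min_estimated_mse =
          vapply(kv, function(k) theoretical_mse(lam, k, a_ols, sg2), 0),
        fixed = NULL)
      if (config$strategy == "fixed") {
        kstar <- empirical_quantile(sort(km[, j]), config$gamma)
        gsel[v, j] <- config$gamma
      } else {
        i <- max(which(crit == min(crit)))
        kstar <- kv[i]
        gsel[v, j] <- grid[i]
      }
      e <- zy / (lam + kstar) - alpha_true
      sq[v, 6L + j] <- sum(e * e)
    }
  }
  mse <- colMeans(sq, na.rm = TRUE)
  mc_se <- apply(sq, 2L, function(col) stats::sd(col, na.rm = TRUE) / sqrt(sum(!is.na(col))))
  pm <- if (bqr) {
    stats::setNames(vapply(1:5, function(j)
      p_mse(mse[1L + j], mse[6L + j]), 0), .rule_labels)
  } else NULL
  mg <- if (bqr) stats::setNames(colMeans(gsel, na.rm = TRUE), .rule_labels) else NULL
  structure(list(mse = mse, mc_se = mc_se, p_mse = pm, mean_gamma = mg,
                 n_redraws = redraws, config = config),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, digits = 4, ...) {
  print(x$config)
  tab <- data.frame(mse = x$mse, mc_se = x$mc_se)
  print(round(tab, digits))
  if (!is.null(x$p_mse)) {
    cat("P_MSE (% reduction vs baseline):\n")
    print(round(x$p_mse, 1))
  }
  invisible(x)
}

#' Scenario grids of the evaluation design
#'
#' Cases 1--3 cross `sigma2 in {0.5, 1, 5}` with
#' `rho in {0.70, 0.80, 0.90, 0.99}` at `(n, p)` = (25, 4), (50, 8) and
#' (100, 10) respectively. Case 4 fixes `n = 200`, `sigma2 = 1`,
#' `rho = 0.99` and varies `p in {4, 8, 10, 16, 32}`.
#'
#' @param case `"case1"` ... `"case4"`.
#' @param M,B,strategy,error_dist,seed Passed to every [scenario_config()];
#'   scenario seeds are derived from `seed` so the scenarios are
#'   independent.
#' @return List of `"scenario_config"` objects.
#' @export
case_grid_configs <- function(case, M = 1000L, B = 200L, strategy = "oracle",
                              error_dist = "normal", seed = 1L) {
  if (!is.character(case) || length(case) != 1L ||
      !case %in% c("case1", "case2", "case3", "case4"))
    bqr_stop("bqridge_config_error",
             sprintf("unknown case label '%s'", as.character(case)[1L]))
  np <- switch(case, case1 = c(25L, 4L), case2 = c(50L, 8L), case3 = c(100L, 10L),
               case4 = c(200L, NA))
  cfgs <- list()
  i <- 0L
  if (case == "case4") {
    for (p in c(4L, 8L, 10L, 16L, 32L)) {
      i <- i + 1L
      cfgs[[i]] <- scenario_config(200L, p, 0.99, 1, error_dist, M = M, B = B,
                                   strategy = strategy,
                                   seed = derive_seed(seed, i))
    }
  } else {
    for (s2 in c(0.5, 1, 5)) for (rho in c(0.70, 0.80, 0.90, 0.99)) {
      i <- i + 1L
      cfgs[[i]] <- scenario_config(np[1L], np[2L], rho, s2, error_dist,
                                   M = M, B = B, strategy = strategy,
                                   seed = derive_seed(seed, i))
    }
  }
  cfgs
}

#' Run a full case grid
#'
#' Expands a case label via [case_grid_configs()] and runs every scenario.
#'
#' @inheritParams case_grid_configs
#' @param bqr Passed to [run_scenario()].
#' @return List of `"scenario_result"` objects.
#' @export
run_case_grid <- function(case, M = 1000L, B = 200L, strategy = "oracle",
                          error_dist = "normal", seed = 1L, bqr = TRUE) {
  lapply(case_grid_configs(case, M, B, strategy, error_dist, seed),
         run_scenario, bqr = bqr)
}

#' Tidy table of scenario results
#'
#' One row per (scenario x estimator): columns `n, p, rho, sigma2,
#' error_dist, estimator, variant, mse, mc_se, p_mse, mean_gamma`.
#'
#' @param results A `"scenario_result"` or list of them.
#' @return A `data.frame`.
#' @export
scenario_results_table <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    cfg <- r$config
    lab <- names(r$mse)
    base <- sub("^BQR_", "", lab)
    variant <- ifelse(grepl("^BQR_", lab), "bqr",
                      ifelse(lab == "OLS", "ols", "baseline"))
    data.frame(n = cfg$n, p = cfg$p, rho = cfg$rho, sigma2 = cfg$sigma2,
               error_dist = cfg$error_dist, estimator = base,
               variant = variant, mse = unname(r$mse),
               mc_se = unname(r$mc_se),
               p_mse = ifelse(variant == "bqr", unname(r$p_mse[base]), NA_real_),
               mean_gamma = ifelse(variant == "bqr" & !is.null(r$mean_gamma),
                                   unname(r$mean_gamma[base]), NA_real_),
               row.names = NULL)
  }))
}

#' Pivot a tidy results table into the wide report layout
#'
#' Rows are scenarios, columns are `OLS`, each baseline and its
#' bootstrap-quantile version side by side.
#'
#' @param tab Output of [scenario_results_table()].
#' @return A wide `data.frame`.
#' @export
pivot_mse_table <- function(tab) {
  key <- interaction(tab$n, tab$p, tab$rho, tab$sigma2, tab$error_dist, drop = TRUE)
  rows <- lapply(split(tab, key), function(d) {
    out <- d[1L, c("n", "p", "rho", "sigma2", "error_dist")]
    out$OLS <- d$mse[d$estimator == "OLS"]
    for (r in c("HK", "HKB", "HSL", "AM", "GM")) {
      out[[r]] <- d$mse[d$estimator == r & d$variant == "baseline"]
      b <- d$mse[d$estimator == r & d$variant == "bqr"]
      out[[paste0(r, "_bq")]] <- if (length(b)) b else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$n, out$p, out$sigma2, out$rho), , drop = FALSE]
}
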