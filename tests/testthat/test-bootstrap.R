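test_that("pairs resampling preserves pairing and is seed-deterministic", {
  prob <- make_problem(8, 2, 0.5, 1, 31)
  set.seed(1); r1 <- resample_pairs(prob$data)
  set.seed(1); r2 <- resample_pairs(prob$data)
  expect_identical(r1, r2)
  # every resampled row is one of the original (X, y) pairs
  orig <- cbind(prob$data$X, prob$data$y)
  res <- cbind(r1$X, r1$y)
  for (j in seq_len(nrow(res)))
    expect_true(any(apply(orig, 1, function(row) all(row == res[j, ]))))
})

test_that("resampling rows are uniform multinomial draws", {
  set.seed(77)
  X <- matrix(seq_len(5), 5, 1) # n=5 > p=1
  d <- ridge_data(X, 1:5)
  counts <- numeric(5)
  R <- 2000
  for (i in seq_len(R)) {
    r <- resample_pairs(d)
    counts <- counts + tabulate(r$X[, 1], 5)
  }
  expected <- R            # each row expected once per draw of n rows
  se <- sqrt(R * 5 * (1 / 5) * (4 / 5))
  expect_true(all(abs(counts - expected) < 3 * se))
})

test_that("bootstrap distribution is sorted, finite and seed-stable", {
  prob <- make_problem(25, 4, 0.95, 1, 41)
  st <- bootstrap_settings(B = 100, seed = 5)
  d1 <- bootstrap_k_distribution(prob$data, "HK", st)
  d2 <- bootstrap_k_distribution(prob$data, "HK", st)
  expect_identical(d1$values, d2$values)
  expect_length(d1$values, 100)
  expect_true(all(is.finite(d1$values)) && all(d1$values >= 0))
  expect_true(!is.unsorted(d1$values))
})

test_that("noiseless data give an all-zero bootstrap distribution", {
  set.seed(4)
  X <- generate_design(20, 3, 0.7)
  d <- ridge_data(X, as.numeric(X %*% c(1, 2, -1)))
  dist <- bootstrap_k_distribution(d, "GM", bootstrap_settings(B = 50, seed = 2))
  expect_lt(max(dist$values), 1e-10)
})

test_that("a user-supplied rule function is bootstrapped too", {
  prob <- make_problem(25, 3, 0.8, 1, 51)
  my_rule <- function(d) unname(k_hkb(ols_alpha(canonical_decompose(d), d$y)$alpha,
                                      sigma2_hat(d)))
  st <- bootstrap_settings(B = 60, seed = 9)
  d_fun <- bootstrap_k_distribution(prob$data, my_rule, st)
  d_lab <- bootstrap_k_distribution(prob$data, "HKB", st)
  expect_equal(d_fun$values, d_lab$values, tolerance = 1e-10)
})

test_that("bootstrap distribution brackets the full-sample estimate", {
  hits <- 0L
  for (i in 1:60) {
    prob <- make_problem(25, 3, 0.9, 1, 600 + i)
    k_full <- unname(k_estimate_all(prob$data)["HK"])
    dist <- bootstrap_k_distribution(prob$data, "HK",
                                     bootstrap_settings(B = 200, seed = i))
    if (min(dist$values) <= k_full && k_full <= max(dist$values)) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.95)
})

test_that("empirical quantile is the ceiling-order statistic", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(empirical_quantile(v, 0.5), 3)
  expect_equal(empirical_quantile(v, 0.8), 4)
  expect_equal(empirical_quantile(v, 0.999), 5)   # gamma -> 1 gives the maximum
  expect_equal(empirical_quantile(v, c(0.1, 0.9)), c(1, 5))
  expect_error(empirical_quantile(v, 0), class = "bqridge_domain_error")
  expect_error(empirical_quantile(v, 1), class = "bqridge_domain_error")
  # non-decreasing in gamma on a random distribution
  set.seed(8)
  vals <- rexp(37)
  g <- seq(0.05, 0.95, 0.05)
  expect_true(!is.unsorted(empirical_quantile(vals, g)))
})

test_that("quantiles satisfy the defining probability inequality", {
  set.seed(13)
  vals <- sort(rexp(200))
  for (g in c(0.25, 0.5, 0.75, 0.9)) {
    q <- empirical_quantile(vals, g)
    expect_lte(mean(vals < q), g)
    expect_gte(mean(vals <= q), g)
  }
})

test_that("quantiles stabilise as B grows", {
  prob <- make_problem(30, 3, 0.9, 1, 71)
  q <- vapply(c(50, 200, 800, 2000), function(B) {
    dist <- bootstrap_k_distribution(prob$data, "HKB",
                                     bootstrap_settings(B = B, seed = 3))
    empirical_quantile(dist, 0.9)
  }, 0)
  gaps <- abs(diff(q))
  expect_lt(gaps[3], gaps[1] + 1e-8)
})

test_that("gamma selection: fixed, argmin contract, and tie-breaking", {
  prob <- make_problem(25, 4, 0.95, 1, 81)
  st1 <- bootstrap_settings(B = 100, seed = 4, gamma_grid = 0.7)
  dist <- bootstrap_k_distribution(prob$data, "HK", st1)
  sel <- select_gamma(prob$data, dist, st1, strategy = "fixed")
  expect_equal(sel$gamma, 0.7)
  expect_equal(sel$k_star, empirical_quantile(dist, 0.7))
  st <- bootstrap_settings(B = 100, seed = 4)
  sel2 <- select_gamma(prob$data, dist, st, strategy = "min_estimated_mse")
  # the selected level attains the plug-in criterion minimum over the grid
  fcq <- empirical_quantile(dist, st$gamma_grid)
  dec <- canonical_decompose(prob$data)
  a <- ols_alpha(dec, prob$data$y)$alpha
  s2 <- sigma2_hat(prob$data)
  crit <- vapply(fcq, function(k) theoretical_mse(dec$lambdas, k, a, s2), 0)
  expect_equal(sel2$criterion_value, min(crit))
  expect_equal(sel2$k_star, empirical_quantile(dist, sel2$gamma))
  expect_error(select_gamma(prob$data, dist, st, strategy = "oracle"),
               class = "bqridge_config_error")
})

test_that("oracle selection never does worse than any other grid level", {
  prob <- make_problem(25, 4, 0.99, 0.5, 91)
  st <- bootstrap_settings(B = 200, seed = 6)
  dist <- bootstrap_k_distribution(prob$data, "HK", st)
  truth <- list(alpha = prob$truth$alpha, sigma2 = prob$sigma2)
  sel <- select_gamma(prob$data, dist, st, strategy = "oracle", truth = truth)
  lam <- prob$truth$lambdas
  for (g in st$gamma_grid) {
    k_g <- empirical_quantile(dist, g)
    expect_lte(sel$criterion_value,
               theoretical_mse(lam, k_g, truth$alpha, truth$sigma2) + 1e-12)
  }
  # selected k stays inside the bootstrap range
  expect_gte(sel$k_star, min(dist$values))
  expect_lte(sel$k_star, max(dist$values))
})

test_that("bqr_fit is end-to-end deterministic and collapses to OLS when noiseless", {
  set.seed(14)
  X <- generate_design(20, 3, 0.8)
  d0 <- ridge_data(X, as.numeric(X %*% c(2, -1, 1)))
  f0 <- bqr_fit(d0, "HK", bootstrap_settings(B = 50, seed = 2))
  expect_equal(f0$selection$k_star, 0, tolerance = 1e-18)
  dec <- canonical_decompose(d0)
  expect_equal(f0$estimate$alpha, ols_alpha(dec, d0$y)$alpha, tolerance = 1e-9)
  prob <- make_problem(25, 4, 0.9, 1, 101)
  st <- bootstrap_settings(B = 100, seed = 17)
  f1 <- bqr_fit(prob$data, "AM", st)
  f2 <- bqr_fit(prob$data, "AM", st)
  expect_identical(f1$selection, f2$selection)
  expect_identical(f1$beta, f2$beta)
})

test_that("paired Monte Carlo: oracle BQR-HK beats baseline HK at high collinearity", {
  cfg <- scenario_config(25, 4, 0.99, 0.5, M = 150, B = 200, seed = 2024)
  r <- run_scenario(cfg)
  expect_lt(r$mse[["BQR_HK"]], r$mse[["HK"]])
})
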