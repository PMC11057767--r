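test_that("ridge_data validates shape and finiteness", {
  X <- matrix(rnorm(20), 10, 2)
  d <- ridge_data(X, rnorm(10))
  expect_s3_class(d, "ridge_data")
  expect_equal(c(d$n, d$p), c(10, 2))
  expect_error(ridge_data(X, rnorm(9)), class = "bqridge_dimension_error")
  expect_error(ridge_data(matrix(1, 2, 3), rnorm(2)), class = "bqridge_invalid_data")
  Xb <- X; Xb[3, 1] <- NA
  expect_error(ridge_data(Xb, rnorm(10)), class = "bqridge_invalid_data")
})

test_that("decomposition recovers known eigenstructure", {
  # orthonormal columns padded with a zero row: unit eigenvalues
  X <- rbind(diag(2), 0)
  dec <- canonical_decompose(X)
  expect_equal(dec$lambdas, c(1, 1))
  # duplicated column: rank deficiency shows as a zero eigenvalue
  cc <- rnorm(8)
  dec2 <- canonical_decompose(cbind(cc, cc))
  expect_equal(min(dec2$lambdas), 0, tolerance = 1e-12)
})

test_that("eigenvalues match the characteristic-polynomial oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(30), 10, 3)
    dec <- canonical_decompose(X)
    expect_equal(dec$lambdas, charpoly_eigenvalues_3x3(crossprod(X)),
                 tolerance = 1e-8)
  }
})

test_that("decomposition invariants hold and are deterministic", {
  set.seed(11)
  X <- generate_design(15, 4, 0.8)
  dec <- canonical_decompose(X)
  expect_equal(crossprod(dec$U), diag(4), tolerance = 1e-10)
  expect_equal(dec$Z, X %*% dec$U)
  expect_equal(crossprod(dec$Z), diag(dec$lambdas), tolerance = 1e-8)
  expect_true(all(diff(dec$lambdas) <= 0))
  # sign convention makes repeated decompositions identical
  expect_identical(dec$U, canonical_decompose(X)$U)
  expect_error(canonical_decompose(matrix(c(1, Inf, 2, 3), 2, 2)),
               class = "bqridge_invalid_data")
})

test_that("canonical OLS equals the normal-equations solution", {
  for (seed in 1:10) {
    prob <- make_problem(20, 3, 0.7, 1, seed)
    dec <- canonical_decompose(prob$data)
    a <- ols_alpha(dec, prob$data$y)
    beta_direct <- solve(crossprod(prob$data$X), crossprod(prob$data$X, prob$data$y))[, 1]
    expect_equal(to_original_space(a, dec)$alpha, beta_direct, tolerance = 1e-8)
  }
})

test_that("canonical OLS recovers noiseless truth and maps orthogonal y to zero", {
  set.seed(2)
  X <- generate_design(12, 3, 0.5)
  dec <- canonical_decompose(X)
  alpha <- c(2, -1, 0.5)
  a <- ols_alpha(dec, dec$Z %*% alpha)
  expect_equal(a$alpha, alpha, tolerance = 1e-10)
  # residual-space vector: project random noise off the column space
  e <- rnorm(12)
  e_perp <- e - dec$Z %*% solve(crossprod(dec$Z), crossprod(dec$Z, e))
  expect_equal(ols_alpha(dec, e_perp)$alpha, rep(0, 3), tolerance = 1e-10)
})

test_that("OLS refuses numerically singular designs, naming the index", {
  cc <- rnorm(9)
  dec <- canonical_decompose(cbind(cc, cc, rnorm(9)))
  err <- tryCatch(ols_alpha(dec, rnorm(9)), error = identity)
  expect_s3_class(err, "bqridge_singular")
  expect_match(conditionMessage(err), "3")
})

test_that("ridge solution: identity at k=0, direct substitution, shrinkage limit", {
  prob <- make_problem(20, 3, 0.8, 1, 4)
  dec <- canonical_decompose(prob$data)
  expect_equal(ridge_alpha(dec, prob$data$y, 0)$alpha,
               ols_alpha(dec, prob$data$y)$alpha)
  # lambda = (2, 1), Z'y = (4, 3), k = 1 -> (4/3, 3/2)
  Z <- cbind(c(sqrt(2), 0, 0), c(0, 1, 0))
  dec2 <- canonical_decompose(Z)
  y2 <- Z %*% solve(crossprod(Z), c(4, 3))
  expect_equal(ridge_alpha(dec2, y2, 1)$alpha, c(4 / 3, 3 / 2))
  # enormous k annihilates the estimate
  expect_lt(sqrt(sum(ridge_alpha(dec, prob$data$y, 1e9)$alpha^2)), 1e-6)
  expect_error(ridge_alpha(dec, prob$data$y, -0.1), class = "bqridge_domain_error")
})

test_that("ridge agrees with the direct penalised solver on 50 seeded instances", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(15:40, 1); p <- sample(2:6, 1)
    X <- generate_design(n, p, runif(1, 0, 0.95))
    y <- rnorm(n)
    k <- rexp(1)
    dec <- canonical_decompose(X)
    beta_pkg <- to_original_space(ridge_alpha(dec, y, k), dec)$alpha
    beta_direct <- solve(crossprod(X) + k * diag(p), crossprod(X, y))[, 1]
    expect_equal(beta_pkg, beta_direct, tolerance = 1e-8)
  }
})

test_that("shrinkage is monotone in k", {
  prob <- make_problem(25, 4, 0.9, 1, 9)
  dec <- canonical_decompose(prob$data)
  norms <- vapply(c(0, 0.1, 1, 10, 100),
                  function(k) sum(ridge_alpha(dec, prob$data$y, k)$alpha^2), 0)
  expect_true(all(diff(norms) <= 0))
})

test_that("sigma2_hat is the residual mean square", {
  # noiseless: zero
  set.seed(5)
  X <- generate_design(12, 3, 0.6)
  dec <- canonical_decompose(X)
  y0 <- dec$Z %*% c(1, 2, 3)
  d0 <- ridge_data(X, y0)
  expect_equal(sigma2_hat(d0), 0, tolerance = 1e-12)
  # constructed residual vector (1,-1,1,-1) with n=4, p=2: 4/2 = 2
  Z <- cbind(c(1, 1, 1, 1) / 2, c(1, 1, -1, -1) / 2)
  e <- c(1, -1, 1, -1)          # orthogonal to both columns
  y <- Z %*% c(3, -2) + e
  expect_equal(sigma2_hat(ridge_data(Z, y)), 2)
})

test_that("sigma2_hat is unbiased in a Monte Carlo check", {
  est <- numeric(500)
  for (i in seq_len(500)) {
    set.seed(1000 + i)
    X <- generate_design(200, 4, 0.7)
    y <- as.numeric(X %*% generate_true_coefficients(X)$beta) + rnorm(200)
    est[i] <- sigma2_hat(ridge_data(X, y))
  }
  expect_equal(mean(est), 1, tolerance = 0.05)
})

test_that("theoretical MSE: closed-form values and coordinate-wise optimality", {
  expect_equal(theoretical_mse(c(1, 1), 0, c(1, 1), 1), 2)
  expect_equal(theoretical_mse(c(4, 1), 1, c(1, 1), 1), 0.70)
  # k = 0 equals the OLS risk sigma2 * sum(1/lambda) exactly
  lam <- c(9.1, 2.3, 0.4)
  expect_equal(theoretical_mse(lam, 0, c(1, 2, 3), 1.7), 1.7 * sum(1 / lam),
               tolerance = 1e-14)
  # classical per-coordinate optimum k_w = sigma2 / alpha_w^2
  alpha <- c(1.5, -0.7, 0.3); s2 <- 1.3
  k_opt <- s2 / alpha^2
  m_opt <- theoretical_mse(lam, k_opt, alpha, s2)
  expect_lte(m_opt, theoretical_mse(lam, 0, alpha, s2))
  for (kk in exp(seq(log(0.01), log(100), length.out = 40)))
    expect_lte(m_opt, theoretical_mse(lam, kk, alpha, s2) + 1e-12)
  expect_error(theoretical_mse(lam, 0, c(1, 2), 1), class = "bqridge_dimension_error")
})

test_that("grid search confirms each coordinate's minimiser near sigma2/alpha^2", {
  lam <- c(5, 1); alpha <- c(1, 0.5); s2 <- 2
  for (w in 1:2) {
    kgrid <- exp(seq(log(0.01), log(1000), length.out = 2000))
    vals <- vapply(kgrid, function(kk) {
      kvec <- s2 / alpha^2
      kvec[w] <- kk
      theoretical_mse(lam, kvec, alpha, s2)
    }, 0)
    expect_equal(kgrid[which.min(vals)], s2 / alpha[w]^2, tolerance = 0.02)
  }
})

test_that("rotation to original space round-trips", {
  prob <- make_problem(20, 4, 0.85, 1, 6)
  dec <- canonical_decompose(prob$data)
  a <- ols_alpha(dec, prob$data$y)
  b <- to_original_space(a, dec)
  expect_identical(b$space, "original")
  expect_equal(crossprod(dec$U, b$alpha)[, 1], a$alpha, tolerance = 1e-10)
  a0 <- ridge_alpha(dec, rep(0, prob$data$n), 1)
  expect_equal(to_original_space(a0, dec)$alpha, rep(0, 4))
  expect_error(to_original_space(b, dec), class = "bqridge_invalid_data")
})
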