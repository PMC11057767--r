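# Seeded synthetic regression problems used across the suite. The design
# comes from the package's own collinear generator; the truth is the
# unit-norm top eigenvector so the canonical signal is (1, 0, ..., 0).
make_problem <- function(n = 30, p = 4, rho = 0.9, sigma2 = 1, seed = 1) {
  set.seed(seed)
  X <- generate_design(n, p, rho)
  tm <- generate_true_coefficients(X)
  y <- as.numeric(X %*% tm$beta) + rnorm(n, 0, sqrt(sigma2))
  list(data = ridge_data(X, y), truth = tm, sigma2 = sigma2)
}

# Independent characteristic-polynomial eigenvalue oracle for 3x3 matrices:
# coefficients from the trace, the sum of 2x2 principal minors and the
# determinant, roots via polyroot().
charpoly_eigenvalues_3x3 <- function(S) {
  stopifnot(nrow(S) == 3, ncol(S) == 3)
  tr <- sum(diag(S))
  m2 <- det(S[-1, -1]) + det(S[-2, -2]) + det(S[-3, -3])
  # det(S - x I) = -x^3 + tr x^2 - m2 x + det(S)
  r <- polyroot(c(det(S), -m2, tr, -1))
  sort(Re(r), decreasing = TRUE)
}

write_toy_csv <- function(path, n = 12, p = 3, rho = 0.8, seed = 42) {
  set.seed(seed)
  X <- generate_design(n, p, rho)
  y <- as.numeric(X %*% generate_true_coefficients(X)$beta) + rnorm(n, 0, 0.5)
  df <- data.frame(y = y, X)
  names(df) <- c("y", paste0("x", seq_len(p)))
  write.csv(df, path, row.names = FALSE)
  df
}
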