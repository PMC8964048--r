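test_that("sample covariance matches the unbiased centered formula", {
  M <- cbind(c(1, 2, 3), c(1, 0, -1))
  expect_equal(sample_covariance(M)$values,
               matrix(c(1, -1, -1, 1), 2))
  set.seed(1)
  X <- matrix(rnorm(134 * 20), 134, 20)
  expect_equal(sample_covariance(X)$values, unname(cov_two_pass(X)),
               tolerance = 1e-12)
  ## translation invariance of the centered formula
  shift <- sweep(X, 2, runif(20, -5, 5), "+")
  expect_equal(sample_covariance(shift)$values,
               sample_covariance(X)$values, tolerance = 1e-10)
  expect_error(sample_covariance(X[1, , drop = FALSE]), "2 timepoints")
  expect_warning(sample_covariance(cbind(X[, 1], 1)), "zero variance")
})

test_that("Pearson correlation scales covariance correctly", {
  S <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(pearson_correlation(lpsconn:::as_covariance(S))$values, S)
  S2 <- matrix(c(4, 3, 3, 9), 2)
  expect_equal(pearson_correlation(lpsconn:::as_covariance(S2))$values[1, 2],
               0.5)
  set.seed(2)
  A <- crossprod(matrix(rnorm(36), 6))
  D <- diag(A)
  expect_equal(pearson_correlation(lpsconn:::as_covariance(A))$values,
               unname(diag(1 / sqrt(D)) %*% A %*% diag(1 / sqrt(D))),
               tolerance = 1e-12)
})

test_that("hard thresholding honours the strict-survival indicator", {
  set.seed(3)
  R <- pearson_correlation(sample_covariance(matrix(rnorm(200), 50, 4)))
  expect_equal(hard_threshold_matrix(R, 1)$values, diag(4))
  expect_equal(hard_threshold_matrix(R, 0)$values, R$values)
  Rb <- diag(2); Rb[1, 2] <- Rb[2, 1] <- 0.4
  expect_equal(hard_threshold_matrix(Rb, 0.4)$values, diag(2))
  expect_error(hard_threshold_matrix(R, 1.5), "tau")
  ## sparsity is monotone in tau
  taus <- seq(0, 1, by = 0.1)
  nnz <- vapply(taus, function(t)
    sum(hard_threshold_matrix(R, t)$values[upper.tri(diag(4))] != 0),
    numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("partial correlations match formula and regression residuals", {
  Theta <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_partial_correlation(Theta)$values[1, 2], 0.5)
  expect_equal(precision_partial_correlation(diag(c(2, 3, 4)))$values,
               diag(3))
  expect_error(precision_partial_correlation(diag(c(1, -1))), "positive")
  set.seed(4)
  X <- matrix(rnorm(4000 * 3), ncol = 3) %*%
    chol(matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  Theta <- solve(cov(X))
  pc <- precision_partial_correlation(Theta)$values
  for (ij in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_equal(pc[ij[1], ij[2]],
                 partial_cor_residual(X, ij[1], ij[2]),
                 tolerance = 1e-8)
})

test_that("graphical lasso satisfies its optimality conditions", {
  set.seed(5)
  X <- matrix(rnorm(200 * 5), 200, 5)
  S <- sample_covariance(X)
  ## rho = 0: unpenalized MLE is the matrix inverse
  expect_equal(glasso(S, 0)$Theta, solve(S$values), tolerance = 1e-6)
  ## fully-penalized regime has the diagonal closed form
  rho_big <- max(abs(S$values[upper.tri(S$values)])) + 0.01
  fb <- glasso(S, rho_big)
  expect_equal(fb$Theta, diag(1 / (diag(S$values) + rho_big)),
               tolerance = 1e-8)
  ## KKT: |(Theta^-1 - S)_ij| <= rho off-diagonal
  f <- glasso(S, 0.1)
  KKT <- solve(f$Theta) - S$values
  expect_lte(max(abs(KKT[upper.tri(KKT)])), 0.1 + 1e-6)
  expect_error(glasso(lpsconn:::as_covariance(matrix(1, 3, 3)), 0),
               "penalty")
})

test_that("graphical lasso objective matches a general-purpose maximizer", {
  set.seed(6)
  for (p in c(3, 4)) {
    X <- matrix(rnorm(60 * p), 60, p)
    S <- cov(X)
    for (rho in c(0.05, 0.2)) {
      f <- glasso(lpsconn:::as_covariance(S), rho)
      oracle <- glasso_prox_gradient(S, rho)
      expect_equal(glasso_objective(f$Theta, S, rho),
                   glasso_objective(oracle, S, rho),
                   tolerance = 1e-6)
    }
  }
})

test_that("graphical lasso sparsity is monotone in the penalty", {
  set.seed(7)
  X <- matrix(rnorm(100 * 6), 100, 6)
  S <- sample_covariance(X)
  rhos <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  nnz <- vapply(rhos, function(r) {
    Th <- glasso(S, r)$Theta
    sum(abs(Th[upper.tri(Th)]) > 1e-8)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("generalized thresholding satisfies its three defining properties", {
  set.seed(8)
  z <- rnorm(1e4, sd = 2)
  lam <- runif(1e4, 0, 2)
  for (fam in c("soft", "hard")) {
    out <- vapply(seq_along(z), function(i)
      generalized_threshold(z[i], lam[i], fam), numeric(1))
    expect_true(all(abs(out) <= abs(z) + 1e-12))          # no growth
    expect_true(all(out[abs(z) <= lam] == 0))             # kill zone
    expect_true(all(abs(out - z) <= lam + 1e-12))         # bounded move
  }
  expect_equal(generalized_threshold(0.3, 0.5), 0)
  expect_equal(generalized_threshold(0.9, 0.5), 0.4)
  expect_error(generalized_threshold(1, 0.5, "banana"))
})

test_that("the concentration radius is monotone, seeded and quantile-exact", {
  set.seed(9)
  M <- matrix(rnorm(100 * 6), 100, 6)
  r1 <- concentration_radius(0.1, M, seed = 3)
  r2 <- concentration_radius(0.35, M, seed = 3)
  r3 <- concentration_radius(0.9, M, seed = 3)
  expect_gte(r1, r2)
  expect_gte(r2, r3)
  expect_lt(concentration_radius(0.999, M, seed = 3), r2)
  expect_lt(concentration_radius(1 - 1e-6, M, seed = 3), 1e-3)
  expect_identical(concentration_radius(0.35, M, seed = 3),
                   concentration_radius(0.35, M, seed = 3))
  expect_error(concentration_radius(0, M), "alpha")
  ## the radius is the empirical (1 - alpha) quantile of resampled
  ## distances (with the zero distance of the observed matrix included)
  d <- lpsconn:::bootstrap_correlation_distances(M, 200L, 3L, "spectral")
  expect_identical(concentration_radius(0.35, M, n_boot = 200, seed = 3),
                   quantile(c(0, d), 0.65, names = FALSE))
})

test_that("sparse covariance estimation collapses correctly in edge cases", {
  set.seed(10)
  ## independent ROIs: thresholding the near-diagonal correlation is
  ## always feasible at lambda -> 1, so the estimate keeps its diagonal
  M <- matrix(rnorm(500 * 5), 500, 5)
  est <- sparse_covariance_estimate(M, alpha = 0.35, seed = 2)
  expect_equal(diag(est$sigma_sp), diag(sample_covariance(M)$values))
  expect_lte(est$distance_final, est$r_alpha)
  expect_gte(est$lambda_final, 0)
  expect_lte(est$lambda_final, 1)
})

test_that("bisection equals exhaustive grid search within resolution", {
  for (s in 1:8) {
    set.seed(s)
    Sig <- diag(10); Sig[1, 2] <- Sig[2, 1] <- 0.6
    Sig[3, 4] <- Sig[4, 3] <- -0.4
    X <- MASS::mvrnorm(200, rep(0, 10), Sig)
    est <- sparse_covariance_estimate(X, alpha = 0.35, seed = s)
    lam_grid <- grid_search_lambda(lpsconn:::safe_correlation(X),
                                   est$r_alpha)
    expect_lte(abs(est$lambda_final - lam_grid), 2^-10)
  }
})

test_that("sparsity of the concentration estimator is monotone in alpha", {
  set.seed(11)
  Sig <- diag(8); Sig[1, 2] <- Sig[2, 1] <- 0.5
  X <- MASS::mvrnorm(150, rep(0, 8), Sig)
  nnz <- vapply(c(0.9, 0.5, 0.2, 0.05), function(a) {
    est <- sparse_covariance_estimate(X, alpha = a, seed = 4)
    sum(est$corr_sp[upper.tri(est$corr_sp)] != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("support is recovered at scale under the default alpha", {
  set.seed(12)
  J <- 12
  Sig <- diag(J)
  true_edges <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  for (k in seq_len(nrow(true_edges)))
    Sig[true_edges[k, 1], true_edges[k, 2]] <-
      Sig[true_edges[k, 2], true_edges[k, 1]] <- 0.5
  X <- MASS::mvrnorm(5000, rep(0, J), Sig)
  est <- sparse_covariance_estimate(X, alpha = 0.35, seed = 9)
  support <- est$corr_sp != 0 & upper.tri(est$corr_sp)
  truth <- Sig != 0 & upper.tri(Sig)
  err <- mean(support != truth)
  expect_lte(err, 0.05)
})

test_that("connectivity from a sparse covariance preserves zeros", {
  set.seed(13)
  X <- MASS::mvrnorm(300, rep(0, 6), diag(6))
  est <- sparse_covariance_estimate(X, alpha = 0.35, seed = 1)
  cm <- connectivity_from_covariance(est)
  expect_identical(cm$values == 0, est$sigma_sp == 0)
  expect_equal(diag(cm$values), rep(1, 6))
  ## matches Pearson scaling of sigma_sp
  expect_equal(cm$values,
               pearson_correlation(
                 lpsconn:::as_covariance(est$sigma_sp))$values,
               tolerance = 1e-12)
})

test_that("the estimator dispatcher composes the primitives faithfully", {
  set.seed(14)
  M <- matrix(rnorm(120 * 7), 120, 7)
  expect_equal(estimate_connectivity(cbind(c(1, 2, 3), c(1, 0, -1)),
                                     "correlation")$values,
               matrix(c(1, -1, -1, 1), 2))
  expect_equal(estimate_connectivity(M, "sparse_correlation", tau = 0.4)$values,
               hard_threshold_matrix(
                 pearson_correlation(sample_covariance(M)), 0.4)$values)
  f <- glasso(sample_covariance(M), 0.1)
  expect_equal(estimate_connectivity(M, "glasso_partial_correlation",
                                     rho = 0.1)$values,
               precision_partial_correlation(f$Theta)$values)
  expect_equal(estimate_connectivity(M, "sparse_partial_correlation",
                                     tau = 0.8)$values,
               hard_threshold_matrix(
                 precision_partial_correlation(
                   solve(sample_covariance(M)$values)), 0.8)$values)
  ## all seven produce symmetric output with the right tag
  for (m in c("correlation", "sparse_correlation", "partial_correlation",
              "sparse_partial_correlation", "glasso_precision",
              "glasso_partial_correlation", "sparse_covariance")) {
    cm <- estimate_connectivity(M, m)
    expect_identical(cm$method, m)
    expect_true(lpsconn:::is_symmetric_num(cm$values))
  }
  ## T < J falls back to the pseudo-inverse with a warning
  Mshort <- matrix(rnorm(5 * 8), 5, 8)
  expect_warning(estimate_connectivity(Mshort, "partial_correlation"),
                 "pseudo-inverse")
})
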