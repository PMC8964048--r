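## Independent oracles used across the test files.  Each reimplements a
## quantity from first principles so the package code path is checked
## against a different computation.

## Textbook two-pass sample covariance (column means first, then
## cross-products with divisor T-1).
cov_two_pass <- function(M) {
  Tn <- nrow(M)
  ctr <- sweep(M, 2, colMeans(M))
  crossprod(ctr) / (Tn - 1)
}

## Partial correlation of variables i and j given all others, via the
## regression-residual route: correlate the residuals of each variable
## regressed on the remaining columns.
partial_cor_residual <- function(M, i, j) {
  others <- setdiff(seq_len(ncol(M)), c(i, j))
  ri <- stats::lm.fit(cbind(1, M[, others, drop = FALSE]), M[, i])$residuals
  rj <- stats::lm.fit(cbind(1, M[, others, drop = FALSE]), M[, j])$residuals
  stats::cor(ri, rj)
}

glasso_objective <- function(Theta, S, rho) {
  determinant(Theta, logarithm = TRUE)$modulus[1] -
    sum(S * Theta) - rho * sum(abs(Theta))
}

## General-purpose convex maximizer for the penalized likelihood:
## proximal gradient ascent on Theta with a positive-definiteness
## backtracking line search.  Independent of the block coordinate
## descent used by glasso().
glasso_prox_gradient <- function(S, rho, max_iter = 50000, tol = 1e-12) {
  Theta <- diag(1 / (diag(S) + rho), nrow(S))
  t_step <- 1 / (norm(S, "2")^2 + 1)
  obj_old <- glasso_objective(Theta, S, rho)
  for (it in seq_len(max_iter)) {
    G <- solve(Theta) - S
    t <- t_step
    repeat {
      Z <- Theta + t * G
      cand <- sign(Z) * pmax(abs(Z) - t * rho, 0)
      ok <- tryCatch({ chol(cand); TRUE }, error = function(e) FALSE)
      if (ok) break
      t <- t / 2
      if (t < 1e-16) { cand <- Theta; break }
    }
    Theta <- (cand + t(cand)) / 2
    if (it %% 100 == 0) {
      obj <- glasso_objective(Theta, S, rho)
      if (abs(obj - obj_old) < tol) break
      obj_old <- obj
    }
  }
  Theta
}

## Exhaustive threshold search: largest lambda on a dyadic grid whose
## thresholded correlation matrix stays within r of the original.
grid_search_lambda <- function(R0, r, k_max = 10L,
                               family = "soft", metric = "spectral") {
  grid <- seq(0, 1, by = 2^(-k_max))
  feasible <- vapply(grid, function(l) {
    Rl <- generalized_threshold(R0, l, family)
    diag(Rl) <- diag(R0)
    lpsconn:::matrix_distance(Rl, R0, metric) <= r
  }, logical(1))
  max(grid[feasible])
}

## Small planted L0 + S0 instance for recovery tests.
planted_lps <- function(n, m, rank, spike_frac, spike_mag, seed) {
  set.seed(seed)
  L0 <- matrix(rnorm(n * rank), n) %*% t(matrix(rnorm(m * rank), m))
  S0 <- matrix(0, n, m)
  pos <- sample(n * m, round(spike_frac * n * m))
  S0[pos] <- spike_mag * sample(c(-1, 1), length(pos), replace = TRUE)
  list(L0 = L0, S0 = S0, M = L0 + S0)
}

## Symmetric p-value matrix from an upper-triangle vector (column-major
## edge order), diagonal 1.
symmetric_p <- function(v, J)
  lpsconn:::symmetric_from_upper(v, J, diag_value = 1)

## Small two-group tensor used by several pipeline tests.
small_tensor <- function(seed = 7, n_diff = 3, J = 8) {
  generate_group_tensor(synthetic_config(
    n_group0 = 6, n_group1 = 5, n_time = 40, n_roi = J, rank_r = 2,
    outlier_fraction = 0.02, noise_sd = 0.1, n_diff_edges = n_diff,
    effect_size = 0.3, seed = seed, block_size = 3))
}
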