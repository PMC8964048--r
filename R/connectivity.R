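#' Sample covariance over timepoints
#'
#' Unbiased (divisor T-1) column-mean-centered covariance of a T x J
#' signal matrix; columns are ROIs, rows timepoints.  ROIs with exactly
#' zero variance are permitted and flagged.
#'
#' @param M Numeric T x J matrix, T >= 2.
#' @return An object of class \code{covariance_matrix} with \code{values}
#'   (J x J symmetric), \code{n_samples} and \code{zero_variance}
#'   (logical per-ROI flag).
#' @export
sample_covariance <- function(M) {
  if (!is.matrix(M) || !all(is.finite(M))) stop("`M` must be a finite matrix")
  if (nrow(M) < 2) stop("at least 2 timepoints are required")
  V <- stats::cov(M)
  zv <- diag(V) == 0
  if (any(zv))
    warning(sprintf("%d ROI(s) have zero variance", sum(zv)))
  structure(list(values = unname(V), n_samples = nrow(M),
                 zero_variance = unname(zv)),
            class = "covariance_matrix")
}

as_covariance <- function(x, n_samples = NA_integer_) {
  if (inherits(x, "covariance_matrix")) return(x)
  stopifnot(is.matrix(x), is_symmetric_num(x, 1e-8))
  structure(list(values = unname(x), n_samples = n_samples,
                 zero_variance = diag(x) == 0),
            class = "covariance_matrix")
}

new_connectivity <- function(values, method, params = list()) {
  values <- unname((values + t(values)) / 2)  # kill rounding asymmetry
  off <- values[upper.tri(values)]
  structure(list(values = values, method = method, params = params,
                 sparsity_zero = mean(off == 0),
                 sparsity_nonzero = mean(off != 0)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity matrix (%s): %d x %d, %.1f%% zero off-diagonal\n",
              x$method, nrow(x$values), ncol(x$values),
              100 * x$sparsity_zero))
  invisible(x)
}

#' Pearson correlation from a covariance matrix
#'
#' Scales a covariance to correlation, \eqn{r_{pq} = s_{pq} /
#' (s_{pp} s_{qq})^{1/2}}.  ROIs with zero variance get zero
#' off-diagonal entries (diagonal stays 1) with a warning.
#'
#' @param S A \code{\link{sample_covariance}} result or plain symmetric
#'   matrix.
#' @return A \code{connectivity_matrix} with method \code{"correlation"}.
#' @export
pearson_correlation <- function(S) {
  S <- as_covariance(S)
  V <- S$values
  d <- diag(V)
  if (any(d < 0)) stop("covariance diagonal must be non-negative")
  zv <- d == 0
  R <- matrix(0, nrow(V), ncol(V))
  if (any(!zv)) {
    ok <- !zv
    R[ok, ok] <- stats::cov2cor(V[ok, ok, drop = FALSE])
  }
  diag(R) <- 1
  if (any(zv))
    warning(sprintf("%d zero-variance ROI(s): correlations set to 0", sum(zv)))
  new_connectivity(R, "correlation")
}

#' Hard-threshold a correlation-type connectivity matrix
#'
#' Off-diagonal entries survive only when strictly above the threshold
#' in absolute value (\eqn{r \mathbf{1}\{|r| > \tau\}}); the diagonal is
#' forced to 1.  \eqn{\tau = 1} yields the identity matrix; \eqn{\tau =
#' 0} leaves the matrix unchanged.
#'
#' @param R A \code{connectivity_matrix} (correlation-type) or plain
#'   symmetric matrix.
#' @param tau Threshold in [0, 1].
#' @return A \code{connectivity_matrix} with \code{"sparse_"} prepended
#'   to the input method tag.
#' @export
hard_threshold_matrix <- function(R, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("`tau` must be a single number in [0, 1]")
  method <- "correlation"
  params <- list()
  if (inherits(R, "connectivity_matrix")) {
    method <- R$method; params <- R$params; R <- R$values
  }
  R[abs(R) <= tau] <- 0
  diag(R) <- 1
  new_connectivity(R, paste0("sparse_", sub("^sparse_", "", method)),
                   c(params, list(tau = tau)))
}

#' Partial correlations from a precision matrix
#'
#' \eqn{\rho_{pq} = -\theta_{pq} / (\theta_{pp}\theta_{qq})^{1/2}} with
#' unit diagonal.
#'
#' @param Theta Symmetric precision (inverse covariance) matrix with
#'   strictly positive diagonal.
#' @return A \code{connectivity_matrix} with method
#'   \code{"partial_correlation"}.
#' @export
precision_partial_correlation <- function(Theta) {
  if (inherits(Theta, "connectivity_matrix")) Theta <- Theta$values
  stopifnot(is.matrix(Theta), is_symmetric_num(Theta, 1e-8))
  d <- diag(Theta)
  if (any(d <= 0)) stop("precision diagonal must be strictly positive")
  Dm <- 1 / sqrt(d)
  R <- -(Dm * Theta) * rep(Dm, each = nrow(Theta))
  diag(R) <- 1
  new_connectivity(R, "partial_correlation")
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' Maximizes the l1-penalized Gaussian log-likelihood
#' \deqn{\log\det\Theta - \mathrm{tr}(S\Theta) - \rho\|\Theta\|_1}
#' over positive definite matrices by block coordinate descent over
#' columns (each column update is a lasso regression solved by
#' coordinate descent).  The penalty covers all entries including the
#' diagonal, so for \eqn{\rho \ge \max_{i \ne j} |s_{ij}|} the solution
#' is diagonal with \eqn{\hat\theta_{ii} = 1/(s_{ii} + \rho)}.
#'
#' @param S A \code{\link{sample_covariance}} result or symmetric matrix.
#' @param rho Non-negative penalty; \code{rho = 0} returns the
#'   unpenalized inverse (errors if \code{S} is singular).
#' @param tol Convergence tolerance on the mean absolute change of the
#'   working covariance, scaled by the mean absolute off-diagonal of S.
#' @param max_iter Maximum number of full column sweeps.
#' @return A list of class \code{glasso_fit}: \code{Theta} (precision
#'   estimate), \code{W} (its inverse, the covariance estimate),
#'   \code{rho}, \code{iterations}, \code{converged}.
#' @export
glasso <- function(S, rho, tol = 1e-5, max_iter = 200L) {
  S <- as_covariance(S)$values
  p <- nrow(S)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0)
    stop("`rho` must be a single non-negative number")
  if (rho == 0) {
    if (rcond(S) < 1e-12)
      stop("S is (near-)singular and rho = 0: a positive penalty is required")
    Theta <- solve(S)
    Theta <- (Theta + t(Theta)) / 2
    return(structure(list(Theta = Theta, W = S, rho = 0,
                          iterations = 0L, converged = TRUE),
                     class = "glasso_fit"))
  }
  W <- S + rho * diag(p)
  B <- matrix(0, p - 1, p)              # lasso coefficients per column
  s_off <- abs(S[upper.tri(S)])
  thr <- tol * max(mean(s_off), .Machine$double.eps)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      ## coordinate descent on (1/2) b'W11 b - s12'b + rho|b|_1
      for (inner in seq_len(500L)) {
        delta <- 0
        for (k in seq_len(p - 1)) {
          resid <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          new_b <- soft_threshold(resid, rho) / W11[k, k]
          delta <- max(delta, abs(new_b - beta[k]))
          beta[k] <- new_b
        }
        if (delta < 1e-3 * thr) break
      }
      B[, j] <- beta
      w12 <- as.vector(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)[upper.tri(W)]) < thr &&
        it > 1L) { converged <- TRUE; break }
  }
  ## recover Theta from W and the regression coefficients
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- B[, j]
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -beta * theta_jj
  }
  Theta <- (Theta + t(Theta)) / 2
  structure(list(Theta = Theta, W = W, rho = rho,
                 iterations = it, converged = converged),
            class = "glasso_fit")
}

#' Generalized thresholding operator
#'
#' Elementwise shrinkers satisfying the three defining properties of a
#' generalized thresholding rule: never increase magnitude, vanish at
#' or below the threshold, and move a value by at most the threshold.
#' \code{"soft"} shrinks by \code{lam}; \code{"hard"} zeroes at or
#' below \code{lam} and keeps larger values unchanged.
#'
#' @param z Numeric vector or matrix.
#' @param lam Non-negative threshold.
#' @param family \code{"soft"} (default) or \code{"hard"}.
#' @return Same shape as \code{z}.
#' @export
generalized_threshold <- function(z, lam, family = c("soft", "hard")) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0)
    stop("`lam` must be a single non-negative number")
  family <- match.arg(family)
  switch(family,
         soft = soft_threshold(z, lam),
         hard = z * (abs(z) > lam))
}

#' Concentration-set confidence radius by bootstrap calibration
#'
#' Radius \eqn{r_\alpha} of the \eqn{(1-\alpha)} confidence ball around
#' the observed correlation matrix, calibrated by resampling timepoints
#' with replacement: the empirical \eqn{(1-\alpha)} quantile of the
#' distances between resampled correlation matrices and the observed
#' one (the zero distance of the observed matrix itself is included, so
#' \eqn{r_\alpha \to 0} as \eqn{\alpha \to 1}).  Monotone decreasing in
#' \eqn{\alpha} and deterministic given the seed.
#'
#' @param alpha False-positive rate in (0, 1); smaller alpha gives a
#'   larger radius.
#' @param M T x J signal matrix whose timepoints are resampled.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param metric Distance between matrices: \code{"spectral"} (largest
#'   singular value of the difference, the operator norm; default) or
#'   \code{"maxabs"} (largest absolute entry).
#' @return Non-negative scalar radius.
#' @export
concentration_radius <- function(alpha, M, n_boot = 200L, seed = 1L,
                                 metric = c("spectral", "maxabs")) {
  stop_if_not_scalar_prob(alpha, "alpha")
  metric <- match.arg(metric)
  dists <- bootstrap_correlation_distances(M, n_boot, seed, metric)
  stats::quantile(c(0, dists), probs = 1 - alpha, names = FALSE, type = 7)
}

## Bootstrap distance sample shared by concentration_radius and
## sparse_covariance_estimate (so the estimate resamples only once).
bootstrap_correlation_distances <- function(M, n_boot, seed, metric) {
  stopifnot(is.matrix(M), nrow(M) >= 2)
  R_obs <- safe_correlation(M)
  withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(M), nrow(M), replace = TRUE)
      matrix_distance(safe_correlation(M[idx, , drop = FALSE]), R_obs,
                      metric)
    }, numeric(1))
  })
}

## Correlation matrix with zero-variance columns mapped to zero
## correlation (diagonal 1) instead of NaN.
safe_correlation <- function(M) {
  V <- stats::cov(M)
  d <- diag(V)
  zv <- d <= 0
  R <- matrix(0, nrow(V), ncol(V))
  if (any(!zv)) R[!zv, !zv] <- stats::cov2cor(V[!zv, !zv, drop = FALSE])
  diag(R) <- 1
  R
}

#' Concentration-inequality-based sparse covariance estimation
#'
#' Thresholds the sample correlation matrix as aggressively as possible
#' while staying inside a \eqn{(1-\alpha)} confidence ball of radius
#' \eqn{r_\alpha} around it.  The threshold \eqn{\lambda \in [0,1]} is
#' located by the dyadic bisection: start at 1/2 and move up (more
#' sparsity) while the thresholded matrix stays within distance
#' \eqn{r_\alpha} of the sample correlation, halving the step each of
#' \code{k_max} iterations.  The returned \eqn{\lambda} is the largest
#' feasible value visited (so the estimate always lies in the
#' confidence set), and the estimate is rescaled back to covariance:
#' \eqn{\hat\Sigma_{sp} = \hat\Sigma_{diag}^{1/2}\, s_\lambda(R)\,
#' \hat\Sigma_{diag}^{1/2}}.
#'
#' @param M T x J signal matrix.
#' @param alpha False-positive rate in (0, 1); default 0.35.
#' @param k_max Number of bisection steps (default 10, resolution
#'   about \eqn{2^{-10}}).
#' @param family Thresholding family passed to
#'   \code{\link{generalized_threshold}}.
#' @param n_boot,seed Bootstrap calibration of \eqn{r_\alpha}.
#' @param metric Distance metric, see \code{\link{concentration_radius}}.
#' @return An object of class \code{sparse_covariance_estimate}:
#'   \code{sigma_sp}, \code{corr_sp} (the thresholded correlation),
#'   \code{lambda_final}, \code{alpha}, \code{r_alpha}, \code{k_steps},
#'   \code{distance_final}, \code{family}, \code{metric}.
#' @export
sparse_covariance_estimate <- function(M, alpha = 0.35, k_max = 10L,
                                       family = c("soft", "hard"),
                                       n_boot = 200L, seed = 1L,
                                       metric = c("spectral", "maxabs")) {
  stop_if_not_scalar_prob(alpha, "alpha")
  family <- match.arg(family)
  metric <- match.arg(metric)
  S <- sample_covariance(M)
  d <- diag(S$values)
  R0 <- safe_correlation(M)
  dists <- bootstrap_correlation_distances(M, n_boot, seed, metric)
  r_alpha <- stats::quantile(c(0, dists), probs = 1 - alpha,
                             names = FALSE, type = 7)

  threshold_offdiag <- function(lam) {
    Rl <- generalized_threshold(R0, lam, family)
    diag(Rl) <- diag(R0)
    Rl
  }
  feasible <- function(lam)
    matrix_distance(threshold_offdiag(lam), R0, metric) <= r_alpha

  lambda <- 0.5
  best <- 0   # lambda = 0 is always feasible: d(R0, R0) = 0
  for (k in seq_len(k_max)) {
    if (feasible(lambda)) {
      best <- max(best, lambda)
      lambda <- lambda + 2^(-(k + 1))
    } else {
      lambda <- lambda - 2^(-(k + 1))
    }
  }
  lambda_final <- best
  corr_sp <- threshold_offdiag(lambda_final)
  distance_final <- matrix_distance(corr_sp, R0, metric)
  sigma_sp <- sqrt(d) * corr_sp * rep(sqrt(d), each = length(d))
  structure(list(sigma_sp = unname(sigma_sp), corr_sp = unname(corr_sp),
                 lambda_final = lambda_final, alpha = alpha,
                 r_alpha = r_alpha, k_steps = as.integer(k_max),
                 distance_final = distance_final,
                 family = family, metric = metric),
            class = "sparse_covariance_estimate")
}

#' @export
print.sparse_covariance_estimate <- function(x, ...) {
  cat(sprintf(paste0("sparse covariance estimate: %d ROIs, alpha = %.3g\n",
                     "  lambda = %.5g, r_alpha = %.4g, distance = %.4g\n"),
              nrow(x$sigma_sp), x$alpha, x$lambda_final, x$r_alpha,
              x$distance_final))
  invisible(x)
}

#' Connectivity matrix from a sparse covariance estimate
#'
#' Correlation-scales the sparse covariance estimate; the zero pattern
#' is preserved exactly (rescaling never un-zeroes an entry) and the
#' diagonal is 1.
#'
#' @param est A \code{\link{sparse_covariance_estimate}}.
#' @return A \code{connectivity_matrix} with method
#'   \code{"sparse_covariance"}.
#' @export
connectivity_from_covariance <- function(est) {
  stopifnot(inherits(est, "sparse_covariance_estimate"))
  d <- diag(est$sigma_sp)
  if (any(d == 0)) stop("zero diagonal entry in sparse covariance estimate")
  R <- pearson_correlation(as_covariance(est$sigma_sp))
  new_connectivity(R$values, "sparse_covariance",
                   list(alpha = est$alpha, lambda = est$lambda_final,
                        r_alpha = est$r_alpha, family = est$family,
                        metric = est$metric))
}

#' Estimate a connectivity matrix by one of the seven methods
#'
#' Dispatches a T x J signal matrix to the requested estimator:
#' \describe{
#'   \item{correlation}{Pearson correlation of the sample covariance.}
#'   \item{sparse_correlation}{correlation hard-thresholded at
#'     \code{tau} (default 0.4).}
#'   \item{partial_correlation}{partial correlations from the inverse
#'     sample covariance (Moore-Penrose pseudo-inverse with a warning,
#'     or ridge jitter, when near-singular).}
#'   \item{sparse_partial_correlation}{partial correlations
#'     hard-thresholded at \code{tau} (default 0.8).}
#'   \item{glasso_precision}{the graphical-lasso precision estimate
#'     itself (penalty \code{rho}, default 0.1).}
#'   \item{glasso_partial_correlation}{partial correlations of the
#'     graphical-lasso precision.}
#'   \item{sparse_covariance}{correlation-scaled
#'     concentration-inequality sparse covariance estimate
#'     (\code{alpha}, default 0.35).}
#' }
#'
#' @param M T x J signal matrix.
#' @param method One of the seven tags above.
#' @param tau,rho,alpha Method parameters (see above for defaults).
#' @param singular_policy For partial correlations with a singular
#'   sample covariance: \code{"pseudoinverse"} (default) or
#'   \code{"ridge"} (adds a trace-scaled 1e-6 jitter).
#' @param ... Further arguments passed to
#'   \code{\link{sparse_covariance_estimate}} or \code{\link{glasso}}.
#' @return A \code{connectivity_matrix}.
#' @export
estimate_connectivity <- function(M,
                                  method = c("correlation",
                                             "sparse_correlation",
                                             "partial_correlation",
                                             "sparse_partial_correlation",
                                             "glasso_precision",
                                             "glasso_partial_correlation",
                                             "sparse_covariance"),
                                  tau = NULL, rho = 0.1, alpha = 0.35,
                                  singular_policy = c("pseudoinverse",
                                                      "ridge"),
                                  ...) {
  method <- match.arg(method)
  singular_policy <- match.arg(singular_policy)

  partial_from_sample <- function() {
    S <- sample_covariance(M)$values
    if (rcond(S) < 1e-12) {
      if (singular_policy == "ridge") {
        S <- S + 1e-6 * mean(diag(S)) * diag(nrow(S))
        Theta <- solve(S)
      } else {
        warning("sample covariance is near-singular; using pseudo-inverse")
        Theta <- MASS::ginv(S)
        Theta <- (Theta + t(Theta)) / 2
      }
    } else Theta <- solve(S)
    precision_partial_correlation(Theta)
  }

  out <- switch(method,
    correlation = pearson_correlation(sample_covariance(M)),
    sparse_correlation = hard_threshold_matrix(
      pearson_correlation(sample_covariance(M)), tau %||% 0.4),
    partial_correlation = partial_from_sample(),
    sparse_partial_correlation = hard_threshold_matrix(
      partial_from_sample(), tau %||% 0.8),
    glasso_precision = {
      fit <- glasso(sample_covariance(M), rho, ...)
      new_connectivity(fit$Theta, "glasso_precision", list(rho = rho))
    },
    glasso_partial_correlation = {
      fit <- glasso(sample_covariance(M), rho, ...)
      pc <- precision_partial_correlation(fit$Theta)
      new_connectivity(pc$values, "glasso_partial_correlation",
                       list(rho = rho))
    },
    sparse_covariance = connectivity_from_covariance(
      sparse_covariance_estimate(M, alpha = alpha, ...))
  )
  out$method <- method
  out
}
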