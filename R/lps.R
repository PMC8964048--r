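#' Solver settings for the augmented Lagrange multiplier RPCA solver
#'
#' @param tol Relative Frobenius feasibility tolerance on
#'   \eqn{\|M - L - S\|_F / \max(\|M\|_F, 1)}.
#' @param max_iter Outer iteration cap.
#' @param mu0 Initial penalty parameter; default \code{NULL} picks the
#'   standard \eqn{1.25 / \|M\|_2} at solve time.
#' @param rho_mu Penalty growth factor (> 1).
#' @return An object of class \code{solver_settings}.
#' @export
solver_settings <- function(tol = 1e-7, max_iter = 1000L, mu0 = NULL,
                            rho_mu = 1.5) {
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive")
  if (max_iter < 1) stop("`max_iter` must be at least 1")
  if (rho_mu <= 1) stop("`rho_mu` must exceed 1")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 mu0 = mu0, rho_mu = rho_mu),
            class = "solver_settings")
}

#' Elementwise soft-thresholding (shrinkage) operator
#'
#' The proximal operator of \eqn{\tau \|\cdot\|_1}:
#' \eqn{\mathrm{sign}(z)\max(|z| - \tau, 0)} applied elementwise.
#'
#' @param z Numeric scalar, vector or matrix.
#' @param tau Non-negative threshold.
#' @return Same shape as \code{z}.
#' @export
soft_threshold <- function(z, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("`tau` must be a single non-negative number")
  sign(z) * pmax(abs(z) - tau, 0)
}

#' Singular value thresholding operator
#'
#' The proximal operator of \eqn{\tau \|\cdot\|_*}: computes
#' \eqn{M = U \Sigma V^T} and returns
#' \eqn{U\,\mathrm{soft}(\Sigma, \tau)\,V^T}.
#'
#' @param M Numeric matrix with finite entries.
#' @param tau Non-negative threshold on the singular values.
#' @return Matrix of the same shape as \code{M}.
#' @export
singular_value_threshold <- function(M, tau) {
  if (!all(is.finite(M))) stop("`M` must have finite entries")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a single non-negative number")
  sv <- svd(M)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*%
    (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Low-rank plus sparse decomposition by inexact ALM
#'
#' Solves the convex program
#' \deqn{\min_{L,S} \|L\|_* + \lambda \|S\|_1 \quad \mathrm{s.t.}\; L + S = M}
#' by the inexact augmented Lagrange multiplier method: one singular
#' value thresholding step for L and one soft-thresholding step for S
#' per outer iteration, followed by the multiplier update
#' \eqn{Y \leftarrow Y + \mu (M - L - S)} and penalty growth
#' \eqn{\mu \leftarrow \min(\rho \mu, \mu_{max})}.
#'
#' @param M Numeric matrix with finite entries.
#' @param lambda_ Positive sparsity weight; the default
#'   \eqn{1/\sqrt{\max(m, n)}} is the universal choice for this program.
#' @param settings A \code{\link{solver_settings}}.
#' @param mask Optional logical matrix marking observed entries; when
#'   supplied the equality constraint is enforced on observed entries
#'   only (matrix-completion style), which is how cross-validation
#'   holds out entries.
#' @return An object of class \code{lps_decomposition} with elements
#'   \code{L}, \code{S}, \code{lambda}, \code{objective},
#'   \code{iterations}, \code{converged}, \code{rank_L}, \code{nnz_S},
#'   \code{residual} and \code{residual_history}.
#' @export
solve_lps <- function(M, lambda_ = 1 / sqrt(max(dim(M))),
                      settings = solver_settings(), mask = NULL) {
  if (!is.matrix(M) || !all(is.finite(M))) stop("`M` must be a finite matrix")
  if (!is.numeric(lambda_) || length(lambda_) != 1L || lambda_ <= 0)
    stop("`lambda_` must be a single positive number")
  stopifnot(inherits(settings, "solver_settings"))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(M)))
  }

  finish <- function(L, S, iterations, converged, resid, history) {
    sv <- svd(L, nu = 0, nv = 0)$d
    structure(list(
      L = L, S = S, lambda = lambda_,
      objective = sum(sv) + lambda_ * sum(abs(S)),
      iterations = iterations, converged = converged,
      rank_L = numerical_rank(L, sv), nnz_S = sum(S != 0),
      residual = resid, residual_history = history
    ), class = "lps_decomposition")
  }

  if (all(M == 0)) {
    Z <- matrix(0, nrow(M), ncol(M))
    return(finish(Z, Z, 0L, TRUE, 0, numeric(0)))
  }

  norm_two <- svd(M, nu = 0, nv = 0)$d[1]
  norm_fro <- max(sqrt(sum(M^2)), 1)
  mu <- settings$mu0 %||% (1.25 / norm_two)
  mu_max <- mu * 1e7
  ## dual-feasible starting multiplier (Lin et al. scaling); the
  ## multiplier lives on observed entries only
  Y <- M / max(norm_two, max(abs(M)) / lambda_)
  if (!is.null(mask)) Y[!mask] <- 0
  L <- matrix(0, nrow(M), ncol(M))
  S <- matrix(0, nrow(M), ncol(M))
  history <- numeric(settings$max_iter)
  converged <- FALSE
  resid <- Inf
  it <- 0L
  for (it in seq_len(settings$max_iter)) {
    G <- if (is.null(mask)) M else ifelse(mask, M, L + S)
    L <- singular_value_threshold(G - S + Y / mu, 1 / mu)
    S <- soft_threshold(G - L + Y / mu, lambda_ / mu)
    if (!is.null(mask)) S[!mask] <- 0
    Z <- if (is.null(mask)) M - L - S else (M - L - S) * mask
    Y <- Y + mu * Z
    mu <- min(mu * settings$rho_mu, mu_max)
    resid <- sqrt(sum(Z^2)) / norm_fro
    history[it] <- resid
    if (resid < settings$tol) { converged <- TRUE; break }
  }
  finish(L, S, it, converged, resid, history[seq_len(it)])
}

#' @export
print.lps_decomposition <- function(x, ...) {
  cat(sprintf(paste0("L+S decomposition: %dx%d, lambda = %.4g\n",
                     "  rank(L) = %d, nnz(S) = %d, objective = %.6g\n",
                     "  %s in %d iterations (residual %.2e)\n"),
              nrow(x$L), ncol(x$L), x$lambda, x$rank_L, x$nnz_S,
              x$objective,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

#' Per-ROI L+S decomposition of a whole tensor
#'
#' Applies \code{\link{solve_lps}} to every stacked N x T ROI slice and
#' reassembles the low-rank and sparse parts into tensors of the input
#' shape.  Non-convergence of a slice is recorded in the diagnostics,
#' never raised as an error.
#'
#' @param tensor A \code{\link{roi_tensor}}.
#' @param lambda_ Positive sparsity weight shared by all slices;
#'   default \eqn{1/\sqrt{\max(N, T)}}.
#' @param settings A \code{\link{solver_settings}}.
#' @param by_group If \code{TRUE}, decompose each group's rows
#'   separately instead of stacking both groups jointly.
#' @return An object of class \code{lps_tensor_decomposition} with
#'   \code{L_tensor}, \code{S_tensor} (both \code{roi_tensor}s sharing
#'   the input labels) and a per-ROI \code{diagnostics} data frame.
#' @export
decompose_tensor <- function(tensor, lambda_ = NULL,
                             settings = solver_settings(),
                             by_group = FALSE) {
  stopifnot(inherits(tensor, "roi_tensor"))
  d <- dim(tensor$values)
  N <- d[1]; Tt <- d[2]; J <- d[3]
  if (is.null(lambda_)) lambda_ <- 1 / sqrt(max(N, Tt))
  L_arr <- array(0, dim = d)
  S_arr <- array(0, dim = d)
  diag_rows <- vector("list", J)
  groups <- if (by_group) split(seq_len(N), tensor$group_labels)
            else list(all = seq_len(N))
  for (j in seq_len(J)) {
    rank_j <- 0L; iter_j <- 0L; conv_j <- TRUE; resid_j <- 0; nnz_j <- 0L
    for (rows in groups) {
      fit <- solve_lps(tensor$values[rows, , j, drop = FALSE][, , 1],
                       lambda_, settings)
      L_arr[rows, , j] <- fit$L
      S_arr[rows, , j] <- fit$S
      rank_j <- max(rank_j, fit$rank_L)
      iter_j <- max(iter_j, fit$iterations)
      conv_j <- conv_j && fit$converged
      resid_j <- max(resid_j, fit$residual)
      nnz_j <- nnz_j + fit$nnz_S
    }
    diag_rows[[j]] <- data.frame(roi = j, rank_L = rank_j, nnz_S = nnz_j,
                                 iterations = iter_j, converged = conv_j,
                                 residual = resid_j)
  }
  structure(list(
    L_tensor = roi_tensor(L_arr, tensor$group_labels, tensor$roi_labels),
    S_tensor = roi_tensor(S_arr, tensor$group_labels, tensor$roi_labels),
    lambda = lambda_,
    diagnostics = do.call(rbind, diag_rows)
  ), class = "lps_tensor_decomposition")
}

#' Cross-validated choice of the sparsity weight lambda
#'
#' Entry-masking (matrix-completion style) cross-validation: for each
#' fold a random subset of entries of every ROI slice is held out, the
#' decomposition is solved on the observed entries only, and each
#' candidate lambda is scored by the mean squared reconstruction error
#' of L on the held-out entries, averaged over folds and ROIs.  One
#' lambda is selected for all slices (pooled).
#'
#' @param tensor A \code{\link{roi_tensor}}.
#' @param grid Non-empty vector of positive candidate lambdas.
#' @param holdout_fraction Fraction of entries masked per fold, in
#'   (0, 0.5).
#' @param folds Number of folds.
#' @param seed Integer seed controlling the masks.
#' @param settings A \code{\link{solver_settings}}.
#' @return A list with \code{best_lambda} (the grid argmin) and
#'   \code{score_table} (data frame: lambda, per-fold and mean scores).
#' @export
choose_lambda_cv <- function(tensor, grid, holdout_fraction = 0.1,
                             folds = 5L, seed = 1L,
                             settings = solver_settings()) {
  stopifnot(inherits(tensor, "roi_tensor"))
  if (length(grid) == 0) stop("`grid` must be non-empty")
  if (any(grid <= 0)) stop("all grid values must be positive")
  if (holdout_fraction <= 0 || holdout_fraction >= 0.5)
    stop("`holdout_fraction` must lie in (0, 0.5)")
  d <- dim(tensor$values)
  N <- d[1]; Tt <- d[2]; J <- d[3]
  scores <- matrix(NA_real_, length(grid), folds)
  withr::with_seed(seed, {
    for (f in seq_len(folds)) {
      masks <- lapply(seq_len(J), function(j) {
        m <- matrix(TRUE, N, Tt)
        m[sample.int(N * Tt, round(holdout_fraction * N * Tt))] <- FALSE
        m
      })
      for (g in seq_along(grid)) {
        err <- 0; n_held <- 0
        for (j in seq_len(J)) {
          M <- tensor$values[, , j, drop = FALSE][, , 1]
          fit <- solve_lps(M, grid[g], settings, mask = masks[[j]])
          held <- !masks[[j]]
          err <- err + sum((M[held] - fit$L[held])^2)
          n_held <- n_held + sum(held)
        }
        scores[g, f] <- err / n_held
      }
    }
  })
  mean_score <- rowMeans(scores)
  tab <- data.frame(lambda = grid, scores,
                    mean_score = mean_score)
  names(tab)[1 + seq_len(folds)] <- paste0("fold", seq_len(folds))
  list(best_lambda = grid[which.min(mean_score)], score_table = tab)
}
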