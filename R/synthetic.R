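#' Configuration for the synthetic ROI time-series generator
#'
#' Bundles and validates all parameters of the synthetic BOLD tensor
#' generator.  Defaults mirror the study design the pipeline targets:
#' two groups of 33 and 24 subjects, 134 timepoints and 116 ROIs (the
#' AAL-116 parcellation), with a shared low-rank temporal component,
#' sparse outlier spikes and a group difference planted on a small set
#' of ROI pairs of the inter-ROI covariance.
#'
#' @param n_group0,n_group1 Subject counts for group 0 (e.g. controls)
#'   and group 1 (e.g. disease).
#' @param n_time Number of timepoints per subject (T).
#' @param n_roi Number of ROIs (J).
#' @param rank_r Rank of the common temporal component shared across
#'   subjects within each ROI slice.
#' @param outlier_fraction Fraction of tensor entries receiving sparse
#'   spikes, in [0, 1).
#' @param outlier_magnitude Absolute spike amplitude, in units of the
#'   signal standard deviation.
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement
#'   noise added to every entry.
#' @param n_diff_edges Number of upper-triangle ROI pairs whose
#'   covariance differs between the two groups.
#' @param effect_size Covariance difference applied on those pairs
#'   (added with a random sign per pair).
#' @param seed Integer RNG seed; the generator is fully deterministic
#'   given the configuration.
#' @param signal_sd Scale of the covariance-driven multivariate normal
#'   ROI signal; set to 0 to disable that component.
#' @param lowrank_sd Scale of the shared rank-\code{rank_r} temporal
#'   component; set to 0 to disable it.
#' @param base_cor Within-block correlation of the block
#'   compound-symmetric baseline covariance.
#' @param block_size Size of the correlated ROI blocks in the baseline
#'   covariance.
#' @param group_specific_lowrank If \code{TRUE} the low-rank component
#'   is drawn independently per group instead of shared.
#'
#' @return An object of class \code{synthetic_config} (a validated list).
#' @export
synthetic_config <- function(n_group0 = 33L, n_group1 = 24L,
                             n_time = 134L, n_roi = 116L,
                             rank_r = 5L,
                             outlier_fraction = 0.05,
                             outlier_magnitude = 10,
                             noise_sd = 0.1,
                             n_diff_edges = 20L,
                             effect_size = 0.2,
                             seed = 1L,
                             signal_sd = 1,
                             lowrank_sd = 1,
                             base_cor = 0.3,
                             block_size = 4L,
                             group_specific_lowrank = FALSE) {
  counts <- c(n_group0 = n_group0, n_group1 = n_group1, n_time = n_time,
              n_roi = n_roi, rank_r = rank_r)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts (n_group0, n_group1, n_time, n_roi, rank_r) must be positive integers")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("`outlier_fraction` must lie in [0, 1)")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (n_diff_edges < 0 || n_diff_edges > n_roi * (n_roi - 1) / 2)
    stop("`n_diff_edges` must lie in [0, J(J-1)/2]")
  structure(list(
    n_group0 = as.integer(n_group0), n_group1 = as.integer(n_group1),
    n_time = as.integer(n_time), n_roi = as.integer(n_roi),
    rank_r = as.integer(rank_r),
    outlier_fraction = outlier_fraction,
    outlier_magnitude = outlier_magnitude,
    noise_sd = noise_sd,
    n_diff_edges = as.integer(n_diff_edges),
    effect_size = effect_size,
    seed = as.integer(seed),
    signal_sd = signal_sd, lowrank_sd = lowrank_sd,
    base_cor = base_cor, block_size = as.integer(block_size),
    group_specific_lowrank = isTRUE(group_specific_lowrank)
  ), class = "synthetic_config")
}

#' ROI time-series tensor
#'
#' Container for a subjects x timepoints x ROIs array of BOLD values
#' with per-subject group labels and an optional ROI label table.
#'
#' @param values Numeric array of dimension N x T x J; all finite.
#' @param group_labels Factor (or coercible) of length N.
#' @param roi_labels Optional data frame of ROI labels (see
#'   \code{\link{aal116_labels}}).
#' @return An object of class \code{roi_tensor}.
#' @export
roi_tensor <- function(values, group_labels, roi_labels = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-dimensional array (subjects x timepoints x ROIs)")
  if (!all(is.finite(values))) stop("tensor values must all be finite")
  group_labels <- as.factor(group_labels)
  if (length(group_labels) != dim(values)[1])
    stop("`group_labels` length must equal the subject dimension")
  structure(list(values = values, group_labels = group_labels,
                 roi_labels = roi_labels),
            class = "roi_tensor")
}

#' @export
print.roi_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ROI time-series tensor: %d subjects x %d timepoints x %d ROIs\n",
              d[1], d[2], d[3]))
  print(table(group = x$group_labels))
  invisible(x)
}

#' @export
dim.roi_tensor <- function(x) dim(x$values)

## Block compound-symmetric baseline covariance: unit variances,
## correlation `base_cor` inside contiguous blocks of `block_size` ROIs.
build_base_covariance <- function(n_roi, base_cor, block_size) {
  sigma <- diag(n_roi)
  starts <- seq(1L, n_roi, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, n_roi)
    sigma[idx, idx] <- base_cor
    diag(sigma)[idx] <- 1
  }
  # restore diagonal clobbered by block fill
  diag(sigma) <- 1
  sigma
}

#' Generate a two-group synthetic ROI time-series tensor
#'
#' Draws, for each subject, a T x J multivariate normal signal over ROIs
#' with that subject's group covariance; superposes a per-ROI rank-r
#' temporal component shared across subjects (so each stacked N x T ROI
#' slice has a planted low-rank part); adds i.i.d. Gaussian noise; and
#' plants sparse spikes of magnitude \code{outlier_magnitude} with
#' random signs at uniformly sampled tensor positions.  The two group
#' covariances differ by \code{effect_size} on exactly
#' \code{n_diff_edges} randomly chosen ROI pairs.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return A list with elements \code{tensor} (a \code{\link{roi_tensor}})
#'   and \code{truth}, where \code{truth} carries \code{sigma0},
#'   \code{sigma1}, \code{diff_edge_set} (data frame of p < q index
#'   pairs), \code{L_true} and \code{S_true} (N x T x J arrays) and
#'   \code{group_labels}.
#' @export
generate_group_tensor <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  N <- cf$n_group0 + cf$n_group1
  J <- cf$n_roi
  Tt <- cf$n_time

  withr::with_seed(cf$seed, {
    sigma0 <- build_base_covariance(J, cf$base_cor, cf$block_size)
    pairs <- edge_pairs(J)
    diff_idx <- if (cf$n_diff_edges > 0)
      sort(sample.int(nrow(pairs), cf$n_diff_edges)) else integer(0)
    diff_edges <- pairs[diff_idx, , drop = FALSE]
    rownames(diff_edges) <- NULL

    sigma1 <- sigma0
    if (nrow(diff_edges) > 0) {
      signs <- sample(c(-1, 1), nrow(diff_edges), replace = TRUE)
      for (e in seq_len(nrow(diff_edges))) {
        p <- diff_edges$p[e]; q <- diff_edges$q[e]
        sigma1[p, q] <- sigma1[p, q] + signs[e] * cf$effect_size
        sigma1[q, p] <- sigma1[p, q]
      }
    }
    ev0 <- min(eigen(sigma0, symmetric = TRUE, only.values = TRUE)$values)
    ev1 <- min(eigen(sigma1, symmetric = TRUE, only.values = TRUE)$values)
    if (ev0 < 1e-6)
      stop("constructed baseline covariance is not positive definite; ",
           "reduce `base_cor` or `block_size`")
    if (ev1 < 1e-6)
      stop(sprintf(paste0("group-1 covariance is not positive definite ",
                          "(min eigenvalue %.3g); use a smaller `effect_size` ",
                          "or fewer `n_diff_edges`"), ev1))

    groups <- factor(rep(c(0L, 1L), c(cf$n_group0, cf$n_group1)),
                     levels = c(0L, 1L))

    ## shared low-rank structure: subject loadings C (N x r, common to all
    ## ROIs) times per-ROI temporal basis B_j (T x r)
    r <- cf$rank_r
    L_true <- array(0, dim = c(N, Tt, J))
    if (cf$lowrank_sd > 0) {
      make_L <- function(n_sub) {
        C <- matrix(stats::rnorm(n_sub * r), n_sub, r)
        arr <- array(0, dim = c(n_sub, Tt, J))
        for (j in seq_len(J)) {
          B <- matrix(stats::rnorm(Tt * r), Tt, r)
          arr[, , j] <- cf$lowrank_sd / sqrt(r) * (C %*% t(B))
        }
        arr
      }
      if (cf$group_specific_lowrank) {
        L_true[groups == 0L, , ] <- make_L(cf$n_group0)
        L_true[groups == 1L, , ] <- make_L(cf$n_group1)
      } else {
        L_true <- make_L(N)
      }
    }

    values <- L_true
    if (cf$signal_sd > 0) {
      for (i in seq_len(N)) {
        sig <- if (groups[i] == 0L) sigma0 else sigma1
        values[i, , ] <- values[i, , ] +
          cf$signal_sd * MASS::mvrnorm(Tt, mu = rep(0, J), Sigma = sig)
      }
    }
    if (cf$noise_sd > 0)
      values <- values + array(stats::rnorm(length(values), sd = cf$noise_sd),
                               dim = dim(values))

    S_true <- array(0, dim = c(N, Tt, J))
    n_spikes <- round(cf$outlier_fraction * N * Tt * J)
    if (n_spikes > 0) {
      pos <- sample.int(N * Tt * J, n_spikes)
      S_true[pos] <- sample(c(-1, 1), n_spikes, replace = TRUE) *
        cf$outlier_magnitude
      values <- values + S_true
    }

    tensor <- roi_tensor(values, groups)
    truth <- list(sigma0 = sigma0, sigma1 = sigma1,
                  diff_edge_set = diff_edges,
                  L_true = L_true, S_true = S_true,
                  group_labels = groups, seed = cf$seed)
    list(tensor = tensor, truth = truth)
  })
}

#' Extract the stacked N x T matrix of one ROI
#'
#' Row i of the result is subject i's time course at the given ROI;
#' these stacked slices are the inputs of the per-ROI L+S decomposition.
#'
#' @param tensor A \code{\link{roi_tensor}}.
#' @param roi_index ROI index in 1..J.
#' @return An N x T numeric matrix.
#' @export
stack_roi_slice <- function(tensor, roi_index) {
  stopifnot(inherits(tensor, "roi_tensor"))
  J <- dim(tensor$values)[3]
  if (!is.numeric(roi_index) || length(roi_index) != 1L ||
      roi_index != round(roi_index) || roi_index < 1 || roi_index > J)
    stop(sprintf("`roi_index` must be an integer in 1..%d", J))
  tensor$values[, , roi_index, drop = TRUE]
}
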