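## Edgewise two-sample testing, significance summaries, the overlap-rate
## consistency statistic and bootstrap stability.

connectivity_values <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$values else x
}

#' Edgewise two-sample t-tests between groups of connectivity matrices
#'
#' For every upper-triangle ROI pair (p, q) the per-subject connectivity
#' values of the two groups are compared with a two-sample t-test
#' (Welch by default, pooled-variance selectable); p-values are
#' mirrored to the lower triangle and the diagonal is set to 1.  Edges
#' with zero variance in both groups (common after hard thresholding
#' zeroes an edge for every subject) get p = 1 and are flagged.
#'
#' @param group0,group1 Lists of \code{connectivity_matrix} objects (or
#'   plain J x J matrices), at least 2 per group, all with the same J.
#' @param variant \code{"welch"} (default) or \code{"pooled"}.
#' @return An object of class \code{edge_pvalue_matrix}: \code{values}
#'   (J x J symmetric p-values), \code{n0}, \code{n1},
#'   \code{test_variant}, \code{adjusted} (FALSE here),
#'   \code{degenerate} (logical vector over upper-triangle edges).
#' @export
edgewise_ttest <- function(group0, group1, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  m0 <- lapply(group0, connectivity_values)
  m1 <- lapply(group1, connectivity_values)
  if (length(m0) < 2 || length(m1) < 2)
    stop("each group needs at least 2 subjects")
  J <- nrow(m0[[1]])
  if (any(vapply(c(m0, m1), function(m) any(dim(m) != J), logical(1))))
    stop("all connectivity matrices must share the same dimension")
  V0 <- do.call(rbind, lapply(m0, upper_values))   # n0 x E
  V1 <- do.call(rbind, lapply(m1, upper_values))
  n0 <- nrow(V0); n1 <- nrow(V1)
  mu0 <- colMeans(V0); mu1 <- colMeans(V1)
  v0 <- apply(V0, 2, stats::var); v1 <- apply(V1, 2, stats::var)

  degenerate <- v0 == 0 & v1 == 0
  if (variant == "welch") {
    se2 <- v0 / n0 + v1 / n1
    tt <- (mu0 - mu1) / sqrt(se2)
    df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  } else {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    tt <- (mu0 - mu1) / sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- rep(n0 + n1 - 2, length(tt))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  p[degenerate] <- 1
  structure(list(values = symmetric_from_upper(p, J, diag_value = 1),
                 n0 = n0, n1 = n1, test_variant = variant,
                 adjusted = FALSE, degenerate = degenerate),
            class = "edge_pvalue_matrix")
}

as_pvalue_matrix <- function(x) {
  if (inherits(x, "edge_pvalue_matrix")) return(x)
  stopifnot(is.matrix(x), is_symmetric_num(x, 1e-8),
            all(x >= 0 & x <= 1))
  structure(list(values = unname(x), n0 = NA_integer_, n1 = NA_integer_,
                 test_variant = NA_character_, adjusted = FALSE,
                 degenerate = rep(FALSE, sum(upper.tri(x)))),
            class = "edge_pvalue_matrix")
}

#' @export
print.edge_pvalue_matrix <- function(x, ...) {
  J <- nrow(x$values)
  cat(sprintf("edgewise p-value matrix: %d ROIs, %d edges (%s t-test%s)\n",
              J, J * (J - 1) / 2,
              x$test_variant,
              if (isTRUE(x$adjusted)) ", BH-adjusted" else ""))
  invisible(x)
}

#' Benjamini-Hochberg adjustment of an edgewise p-value matrix
#'
#' Step-up FDR adjustment over the J(J-1)/2 upper-triangle p-values
#' only, mirrored back to a symmetric matrix.  Adjusted values are
#' entrywise at least the raw values.
#'
#' @param P An \code{\link{edgewise_ttest}} result or symmetric p-value
#'   matrix.
#' @return An \code{edge_pvalue_matrix} with \code{adjusted = TRUE}.
#' @export
bh_adjust <- function(P) {
  P <- as_pvalue_matrix(P)
  J <- nrow(P$values)
  padj <- stats::p.adjust(upper_values(P$values), method = "BH")
  out <- P
  out$values <- symmetric_from_upper(padj, J, diag_value = 1)
  out$adjusted <- TRUE
  out
}

#' Percentage of significant connections
#'
#' Counts upper-triangle edges with p strictly below \code{level} and
#' reports the count as a percentage of the J(J-1)/2 total connections
#' (6,670 for J = 116).
#'
#' @param P An \code{edge_pvalue_matrix} or symmetric p-value matrix.
#' @param level Significance level in (0, 1); default 0.05.
#' @return An object of class \code{significance_summary}: \code{level},
#'   \code{n_significant}, \code{total_edges}, \code{percent},
#'   \code{adjusted}.
#' @export
percent_significant <- function(P, level = 0.05) {
  stop_if_not_scalar_prob(level, "level")
  P <- as_pvalue_matrix(P)
  J <- nrow(P$values)
  pv <- upper_values(P$values)
  n_sig <- sum(pv < level)
  total <- J * (J - 1) / 2
  structure(list(level = level, n_significant = n_sig,
                 total_edges = total,
                 percent = 100 * n_sig / total,
                 adjusted = isTRUE(P$adjusted)),
            class = "significance_summary")
}

#' @export
print.significance_summary <- function(x, ...) {
  cat(sprintf("%d / %d connections significant at %.3g (%.4f%%)%s\n",
              x$n_significant, x$total_edges, x$level, x$percent,
              if (x$adjusted) " [BH-adjusted]" else ""))
  invisible(x)
}

#' Top-k most significant ROI pairs
#'
#' Ranks upper-triangle edges by ascending p-value (ties broken by row
#' then column index) and annotates each pair with ROI abbreviations
#' and anatomical classifications when a label table is supplied.
#'
#' @param P An \code{edge_pvalue_matrix} or symmetric p-value matrix.
#' @param labels Optional ROI label table with columns
#'   \code{abbreviation} and \code{classification} (see
#'   \code{\link{aal116_labels}}); row i labels ROI i.
#' @param k Number of pairs to return (default 10); values beyond the
#'   number of edges return all edges.
#' @return A data frame with columns \code{pair}, \code{region1},
#'   \code{classification1}, \code{region2}, \code{classification2},
#'   \code{p_value} (plus \code{roi1}, \code{roi2} indices).
#' @export
top_significant_pairs <- function(P, labels = NULL, k = 10L) {
  P <- as_pvalue_matrix(P)
  J <- nrow(P$values)
  pairs <- edge_pairs(J)
  pv <- upper_values(P$values)
  ord <- order(pv, pairs$p, pairs$q)
  k <- min(max(0L, as.integer(k)), length(ord))
  ord <- ord[seq_len(k)]
  if (is.null(labels)) {
    abbr <- paste0("ROI", seq_len(J))
    cls <- rep(NA_character_, J)
  } else {
    stopifnot(nrow(labels) >= J)
    abbr <- labels$abbreviation[seq_len(J)]
    cls <- labels$classification[seq_len(J)]
  }
  data.frame(pair = seq_len(k),
             region1 = abbr[pairs$p[ord]],
             classification1 = cls[pairs$p[ord]],
             region2 = abbr[pairs$q[ord]],
             classification2 = cls[pairs$q[ord]],
             p_value = pv[ord],
             roi1 = pairs$p[ord], roi2 = pairs$q[ord])
}

#' Overlap rate between original-signal and low-rank p-value matrices
#'
#' Agreement statistic between the significant-edge sets of two
#' analyses at a threshold: over upper-triangle edges,
#' \code{n1} counts edges with \code{level > p_orig > p_low} and
#' \code{n2} edges with \code{p_orig <= p_low < level} (ties counted
#' once, in n2, so identical matrices give rate 1).  The default
#' denominator is the number of edges significant under the original
#' analysis, which bounds the rate in [0, 1]; the literal
#' count-of-nonzero-entries convention is selectable.
#'
#' @param P_orig,P_low \code{edge_pvalue_matrix} objects (or symmetric
#'   matrices) from the original-signal and low-rank analyses.
#' @param level Significance threshold; default 0.05.
#' @param denominator \code{"significant_original"} (default) or
#'   \code{"nonzero_original"}.
#' @return An object of class \code{overlap_rate_result}: \code{n1},
#'   \code{n2}, \code{denominator}, \code{rate}, \code{level},
#'   \code{convention}.
#' @export
overlap_rate <- function(P_orig, P_low, level = 0.05,
                         denominator = c("significant_original",
                                         "nonzero_original")) {
  stop_if_not_scalar_prob(level, "level")
  denominator <- match.arg(denominator)
  po <- upper_values(as_pvalue_matrix(P_orig)$values)
  pl <- upper_values(as_pvalue_matrix(P_low)$values)
  if (length(po) != length(pl))
    stop("p-value matrices must have the same dimension")
  n1 <- sum(po < level & pl < po)
  n2 <- sum(po < level & po <= pl & pl < level)
  denom <- switch(denominator,
                  significant_original = sum(po < level),
                  nonzero_original = sum(po != 0))
  rate <- if (denom > 0) (n1 + n2) / denom else 0
  structure(list(n1 = n1, n2 = n2, denominator = denom, rate = rate,
                 level = level, convention = denominator),
            class = "overlap_rate_result")
}

#' @export
print.overlap_rate_result <- function(x, ...) {
  cat(sprintf("overlap rate at level %.3g: (%d + %d) / %d = %.4f [%s]\n",
              x$level, x$n1, x$n2, x$denominator, x$rate, x$convention))
  invisible(x)
}

#' Overlap rate across a sweep of significance thresholds
#'
#' @param P_orig,P_low As in \code{\link{overlap_rate}}.
#' @param levels Strictly increasing vector of thresholds in (0, 1).
#' @param denominator Passed to \code{\link{overlap_rate}}.
#' @return Data frame with one row per level: \code{level}, \code{n1},
#'   \code{n2}, \code{denominator}, \code{rate}.
#' @export
overlap_rate_sweep <- function(P_orig, P_low, levels,
                               denominator = "significant_original") {
  if (length(levels) == 0) stop("`levels` must be non-empty")
  if (any(diff(levels) <= 0)) stop("`levels` must be strictly increasing")
  rows <- lapply(levels, function(lv) {
    r <- overlap_rate(P_orig, P_low, lv, denominator)
    data.frame(level = lv, n1 = r$n1, n2 = r$n2,
               denominator = r$denominator, rate = r$rate)
  })
  do.call(rbind, rows)
}

#' Bootstrap stability of the percentage of significant connections
#'
#' Stratified bootstrap: each replicate resamples subjects with
#' replacement within each group at its own size, recomputes
#' per-subject connectivity (optionally after re-running the per-ROI
#' L+S decomposition on the resampled stack), runs the edgewise tests,
#' and records the percentage of significant connections.  The report
#' carries all per-replicate percentages and their sample variance.
#'
#' @param tensor A two-group \code{\link{roi_tensor}}.
#' @param method Connectivity method tag, see
#'   \code{\link{estimate_connectivity}}.
#' @param params Named list of method parameters (tau, rho, alpha, ...).
#' @param B Number of bootstrap replicates; default 50.
#' @param level Significance level; default 0.05.
#' @param seed Integer seed; the report is deterministic given it.
#' @param use_lowrank If \code{TRUE}, connectivity is built from the
#'   low-rank component of the resampled tensor.
#' @param refit_decomposition When \code{use_lowrank} is set: re-run
#'   the decomposition per replicate (default, exact) or reuse the
#'   original decomposition's per-subject low-rank slices
#'   (approximate, much faster).
#' @param lambda_,settings Decomposition controls, see
#'   \code{\link{decompose_tensor}}.
#' @param variant t-test variant.
#' @return An object of class \code{bootstrap_stability_report}:
#'   \code{B}, \code{percents}, \code{variance}, \code{seed},
#'   \code{method}, \code{signal}, \code{level}.
#' @export
bootstrap_stability <- function(tensor, method = "correlation",
                                params = list(), B = 50L, level = 0.05,
                                seed = 1L, use_lowrank = FALSE,
                                refit_decomposition = TRUE,
                                lambda_ = NULL,
                                settings = solver_settings(),
                                variant = "welch") {
  stopifnot(inherits(tensor, "roi_tensor"))
  if (B < 2) stop("`B` must be at least 2")
  glev <- levels(tensor$group_labels)
  if (length(glev) != 2) stop("exactly two groups are required")
  idx0 <- which(tensor$group_labels == glev[1])
  idx1 <- which(tensor$group_labels == glev[2])

  base_low <- NULL
  if (use_lowrank && !refit_decomposition)
    base_low <- decompose_tensor(tensor, lambda_, settings)$L_tensor$values

  draws <- withr::with_seed(seed, {
    lapply(seq_len(B), function(b) list(
      i0 = sample(idx0, length(idx0), replace = TRUE),
      i1 = sample(idx1, length(idx1), replace = TRUE)))
  })

  subject_connectivity <- function(arr, i) {
    do.call(estimate_connectivity,
            c(list(M = arr[i, , , drop = FALSE][1, , ], method = method),
              params))
  }

  percents <- vapply(draws, function(dr) {
    sel <- c(dr$i0, dr$i1)
    if (use_lowrank && refit_decomposition) {
      sub <- roi_tensor(tensor$values[sel, , , drop = FALSE],
                        tensor$group_labels[sel])
      arr <- decompose_tensor(sub, lambda_, settings)$L_tensor$values
      rows0 <- seq_along(dr$i0)
      rows1 <- length(dr$i0) + seq_along(dr$i1)
    } else if (use_lowrank) {
      arr <- base_low
      sel <- seq_len(dim(arr)[1])  # index original decomposition directly
      rows0 <- dr$i0; rows1 <- dr$i1
    } else {
      arr <- tensor$values
      rows0 <- dr$i0; rows1 <- dr$i1
    }
    g0 <- lapply(rows0, function(i) subject_connectivity(arr, i))
    g1 <- lapply(rows1, function(i) subject_connectivity(arr, i))
    P <- edgewise_ttest(g0, g1, variant)
    percent_significant(P, level)$percent
  }, numeric(1))

  structure(list(B = as.integer(B), percents = percents,
                 variance = stats::var(percents), seed = as.integer(seed),
                 method = method,
                 signal = if (use_lowrank) "lowrank" else "original",
                 level = level),
            class = "bootstrap_stability_report")
}

#' @export
print.bootstrap_stability_report <- function(x, ...) {
  cat(sprintf(paste0("bootstrap stability (%s, %s signal): B = %d\n",
                     "  mean percent significant %.4f, variance %.6g\n"),
              x$method, x$signal, x$B, mean(x$percents), x$variance))
  invisible(x)
}
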