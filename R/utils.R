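## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
NULL

## Spectral norm (largest singular value); `norm(, "2")` delegates to LAPACK.
spectral_norm <- function(A) norm(A, type = "2")

matrix_distance <- function(A, B, metric = c("spectral", "maxabs")) {
  metric <- match.arg(metric)
  D <- A - B
  if (metric == "spectral") spectral_norm(D) else max(abs(D))
}

## Upper-triangle edge bookkeeping.  Edges are enumerated in the column-major
## order produced by upper.tri(), so values extracted with m[upper.tri(m)]
## line up with the (p, q) pairs returned here (p < q, 1-based).
edge_pairs <- function(J) {
  idx <- which(upper.tri(diag(J)), arr.ind = TRUE)
  data.frame(p = idx[, 1], q = idx[, 2])
}

upper_values <- function(m) m[upper.tri(m)]

## Rebuild a symmetric matrix from its upper-triangle vector (column-major),
## with a constant diagonal.
symmetric_from_upper <- function(v, J, diag_value = 1) {
  m <- matrix(diag_value, J, J)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

is_symmetric_num <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("`%s` must be a single number in (0, 1)", name), call. = FALSE)
}

## Numerical rank with the standard tolerance max(dim) * eps * sigma_max.
numerical_rank <- function(M, sv = NULL) {
  if (is.null(sv)) sv <- svd(M, nu = 0, nv = 0)$d
  if (length(sv) == 0 || sv[1] == 0) return(0L)
  tol <- max(dim(M)) * .Machine$double.eps * sv[1]
  sum(sv > tol)
}
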