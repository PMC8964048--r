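edge_matrices <- function(values) {
  ## 2x2 connectivity matrices whose single edge carries the value
  lapply(values, function(x) matrix(c(1, x, x, 1), 2))
}

test_that("edgewise t-tests match the closed form and t.test", {
  g0 <- edge_matrices(c(0, 1, 2))
  g1 <- edge_matrices(c(3, 4, 5))
  P <- edgewise_ttest(g0, g1, variant = "pooled")
  expect_equal(P$values[1, 2], 2 * pt(-3 * sqrt(3 / 2), df = 4),
               tolerance = 1e-12)
  expect_equal(P$values[1, 2], 0.0213, tolerance = 1e-2)
  ## Welch variant against stats::t.test on random data
  set.seed(1)
  a <- rnorm(8); b <- rnorm(6, mean = 0.5)
  Pw <- edgewise_ttest(edge_matrices(a), edge_matrices(b))
  expect_equal(Pw$values[1, 2], t.test(a, b)$p.value, tolerance = 1e-12)
  Pp <- edgewise_ttest(edge_matrices(a), edge_matrices(b), "pooled")
  expect_equal(Pp$values[1, 2],
               t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  ## symmetry, range, diagonal
  expect_true(lpsconn:::is_symmetric_num(Pw$values))
  expect_identical(diag(Pw$values), c(1, 1))
  expect_error(edgewise_ttest(g0[1], g1), "at least 2")
})

test_that("degenerate zero-variance edges get p = 1", {
  g0 <- edge_matrices(c(0.5, 0.5, 0.5))
  g1 <- edge_matrices(c(0.5, 0.5))
  P <- edgewise_ttest(g0, g1)
  expect_identical(P$values[1, 2], 1)
  expect_true(P$degenerate[1])
})

test_that("t-test calibration holds under the null", {
  set.seed(2)
  reps <- 50; n_edges <- 500
  frac <- replicate(reps, {
    V0 <- matrix(rnorm(10 * n_edges), 10)
    V1 <- matrix(rnorm(12 * n_edges), 12)
    p <- vapply(seq_len(n_edges), function(e) {
      m0 <- mean(V0[, e]); m1 <- mean(V1[, e])
      v0 <- var(V0[, e]); v1 <- var(V1[, e])
      se2 <- v0 / 10 + v1 / 12
      df <- se2^2 / ((v0 / 10)^2 / 9 + (v1 / 12)^2 / 11)
      2 * pt(-abs(m0 - m1) / sqrt(se2), df)
    }, numeric(1))
    mean(p < 0.05)
  })
  binom_sd <- sqrt(0.05 * 0.95 / n_edges)
  expect_lt(abs(mean(frac) - 0.05), 3 * binom_sd)
})

test_that("BH adjustment is a correct monotone step-up over edges", {
  P4 <- symmetric_p(c(0.01, 0.02, 0.03, 0.04, 0.9, 0.9), 4)
  adj <- bh_adjust(P4)
  ups <- adj$values[upper.tri(adj$values)]
  raw <- P4[upper.tri(P4)]
  expect_equal(sort(ups[raw <= 0.04])[1:4], rep(0.06, 4))
  expect_true(all(ups >= raw))
  ## all-equal p-values are unchanged
  Pe <- symmetric_p(rep(0.2, 6), 4)
  expect_equal(bh_adjust(Pe)$values[upper.tri(Pe)], rep(0.2, 6))
  ## matches p.adjust on the upper triangle
  set.seed(3)
  pv <- runif(15)
  Pr <- symmetric_p(pv, 6)
  expect_equal(bh_adjust(Pr)$values[upper.tri(Pr)],
               p.adjust(pv, "BH"))
  ## rejection nesting: BH rejections are a subset of raw rejections
  expect_true(all(which(bh_adjust(Pr)$values[upper.tri(Pr)] < 0.05) %in%
                    which(pv < 0.05)))
})

test_that("percent significant counts the upper triangle strictly", {
  J <- 116
  P <- symmetric_p(rep(1, J * (J - 1) / 2), J)
  s <- percent_significant(P)
  expect_identical(s$total_edges, 6670)
  expect_identical(s$percent, 0)
  pv <- rep(1, 6670); pv[1:667] <- 0.01
  s2 <- percent_significant(symmetric_p(pv, J), 0.05)
  expect_equal(s2$percent, 10)
  ## boundary: p exactly at the level is not significant
  pv3 <- rep(1, 6670); pv3[1] <- 0.05
  expect_identical(percent_significant(symmetric_p(pv3, J))$n_significant,
                   0L)
})

test_that("top pairs are ranked by p with deterministic tie-breaks", {
  J <- 50
  pv <- rep(0.5, J * (J - 1) / 2)
  P <- symmetric_p(pv, J)
  P[5, 40] <- P[40, 5] <- 1e-6
  tp <- top_significant_pairs(P, k = 3)
  expect_identical(c(tp$roi1[1], tp$roi2[1]), c(5L, 40L))
  expect_identical(nrow(top_significant_pairs(P, k = 0)), 0L)
  expect_identical(nrow(top_significant_pairs(P, k = 1e6)),
                   as.integer(J * (J - 1) / 2))
  ## ties broken by row then column
  expect_identical(c(tp$roi1[2], tp$roi2[2]), c(1L, 2L))
  ## labels flow through in atlas style
  labs <- aal116_labels()
  P116 <- symmetric_p(rep(0.5, 6670), 116)
  P116[37, 101] <- P116[101, 37] <- 1e-4  # L.HIP x L.CER7
  tp2 <- top_significant_pairs(P116, labs, k = 1)
  expect_identical(tp2$region1, "L.HIP")
  expect_identical(tp2$classification1, "Limbic lobe")
  expect_identical(tp2$region2, "L.CER7")
  expect_identical(tp2$classification2, "Cerebellum")
})

test_that("overlap rate matches the hand-enumerated worked example", {
  p_orig <- symmetric_p(c(0.01, 0.20, 0.30, 0.02, 0.40, 0.60), 4)
  p_low <- symmetric_p(c(0.005, 0.30, 0.25, 0.03, 0.50, 0.70), 4)
  o <- overlap_rate(p_orig, p_low, 0.05)
  expect_identical(o$n1, 1L)
  expect_identical(o$n2, 1L)
  expect_identical(o$denominator, 2L)
  expect_identical(o$rate, 1)
})

test_that("overlap rate is 1 for identical and 0 for disjoint sets", {
  set.seed(4)
  pv <- runif(45)
  P <- symmetric_p(pv, 10)
  expect_identical(overlap_rate(P, P)$rate, 1)
  a <- rep(0.5, 45); b <- rep(0.5, 45)
  a[1:5] <- 0.01; b[6:10] <- 0.01
  expect_identical(overlap_rate(symmetric_p(a, 10),
                                symmetric_p(b, 10))$rate, 0)
  ## literal printed denominator is selectable
  lit <- overlap_rate(P, P, denominator = "nonzero_original")
  expect_identical(lit$denominator, sum(pv != 0))
})

test_that("the threshold sweep recounts each level consistently", {
  set.seed(5)
  po <- symmetric_p(runif(45), 10)
  pl <- symmetric_p(runif(45), 10)
  levels <- seq(0.01, 0.1, by = 0.01)
  sw <- overlap_rate_sweep(po, pl, levels)
  expect_identical(nrow(sw), 10L)
  for (i in c(1, 5, 10)) {
    o <- overlap_rate(po, pl, levels[i])
    expect_identical(sw$rate[i], o$rate)
    expect_identical(sw$n1[i], o$n1)
  }
  expect_true(all(sw$rate >= 0 & sw$rate <= 1))
  expect_error(overlap_rate_sweep(po, pl, numeric(0)), "non-empty")
  expect_error(overlap_rate_sweep(po, pl, c(0.05, 0.01)), "increasing")
})

test_that("bootstrap stability is seeded, order-invariant and degenerate-safe", {
  g <- small_tensor(seed = 21)
  b1 <- bootstrap_stability(g$tensor, "correlation", B = 6, seed = 9)
  b2 <- bootstrap_stability(g$tensor, "correlation", B = 6, seed = 9)
  expect_identical(b1$percents, b2$percents)
  expect_identical(b1$variance, b2$variance)
  expect_gte(b1$variance, 0)
  expect_identical(length(b1$percents), 6L)
  expect_equal(b1$variance, var(b1$percents))
  ## identical subjects within groups: every replicate equal, variance 0
  arr <- g$tensor$values
  for (i in 2:6) arr[i, , ] <- arr[1, , ]
  for (i in 8:11) arr[i, , ] <- arr[7, , ]
  const <- roi_tensor(arr, g$tensor$group_labels)
  bc <- bootstrap_stability(const, "correlation", B = 5, seed = 2)
  expect_equal(bc$variance, 0)
  expect_error(bootstrap_stability(g$tensor, "correlation", B = 1), "B")
})
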