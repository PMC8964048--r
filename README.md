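# lpsconn

Robust functional brain connectivity from ROI-level BOLD time series,
via low-rank plus sparse decomposition and group-difference testing.

## What it does and for whom

Resting-state fMRI studies compare functional connectivity — a J × J
matrix of dependence between region-of-interest (ROI) time series —
between groups (e.g. normal controls vs. Alzheimer's disease).  BOLD
signals carry noise and sparse outliers that destabilize connectivity
estimates and the edgewise tests built on them.  `lpsconn` is for
researchers who want that comparison to be robust and reproducible.

The pipeline:

1. **L+S decomposition.**  For each ROI, the stacked subjects × time
   matrix M is split by the convex program

       min_{L,S} ‖L‖* + λ‖S‖₁   s.t.  L + S = M,

   solved by inexact augmented Lagrange multipliers: L (nuclear norm,
   sum of singular values) captures the common low-rank temporal
   structure, S the sparse individual variability and outliers.
   Default λ = 1/√max(N, T); entry-masking cross-validation is
   available.

2. **Connectivity estimation** from either the original signals or the
   low-rank component, by seven estimators: Pearson correlation,
   hard-thresholded (sparse) correlation, partial correlation,
   sparse partial correlation, graphical-lasso precision,
   graphical-lasso partial correlation, and a
   concentration-inequality-based sparse covariance estimator that
   finds the largest threshold λ ∈ [0, 1] keeping the thresholded
   correlation matrix inside a (1 − α) confidence ball of radius r_α
   around the sample correlation (dyadic bisection, 10 steps).

3. **Group differences.**  Edgewise two-sample t-tests (Welch default)
   give a symmetric p-value matrix; summaries report the percentage of
   significant connections among the J(J−1)/2 edges, the top-10 ROI
   pairs (annotated with the packaged AAL-116 atlas labels), the
   overlap rate between original-signal and low-rank analyses, and the
   variance of percent-significant across B = 50 stratified bootstrap
   replicates.  Benjamini–Hochberg adjusted matrices are always
   computed alongside the raw ones.

A synthetic-data module generates tensors with known low-rank
structure, planted sparse spikes and group-differing covariance, so
every stage can be validated against ground truth.

## Worked example

```r
library(lpsconn)

g <- generate_group_tensor(synthetic_config(
  n_group0 = 33, n_group1 = 24, n_time = 134, n_roi = 20,
  n_diff_edges = 10, effect_size = 0.25, seed = 1))
dir <- tempfile()
manifest <- write_tensor(g$tensor, dir, truth = g$truth)

res <- run_pipeline(pipeline_config(
  manifest, methods = c("correlation", "sparse_correlation",
                        "sparse_covariance"), seed = 1))
res$percent_table
#>               method   signal  percent n_significant total_edges
#> 1        correlation original 6.315789            12         190
#> 2        correlation  lowrank 9.473684            18         190
#> 3 sparse_correlation original 0.000000             0         190
#> 4 sparse_correlation  lowrank 0.000000             0         190
#> 5  sparse_covariance original 0.000000             0         190
#> 6  sparse_covariance  lowrank 0.000000             0         190
res$overlap_table
#>               method n1 n2 denominator rate
#> 1        correlation  1  2          12 0.25
#> 2 sparse_correlation  0  0           0 0.00
#> 3  sparse_covariance  0  0           0 0.00
res$lambda
#> [1] 0.08638684
```

Reading it: with 20 ROIs there are 190 testable edges.  The raw
correlation method flags 6.3% of edges on the original signals and
9.5% on the low-rank component — the decomposition increases
detectability of the planted group difference (10 edges of covariance
effect 0.25).  The thresholded estimators report 0% here because a
0.25 covariance effect on a 0.3-correlation background falls below
their default thresholds (τ = 0.4, α = 0.35), zeroing those edges for
every subject; such edges get p = 1 by the degenerate-edge policy.
The overlap rate 0.25 says a quarter of the originally significant
edges stay significant in the low-rank analysis.  The selected λ for
the 57 × 134 slices is 1/√134 ≈ 0.086, and the per-ROI diagnostics
(`res$decomposition$diagnostics`) show the slice rank dropping from 57
to ≈ 37.

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "lpsconn.R", package = "lpsconn"))') \
  simulate --n-roi 20 --seed 1 --out data/
```

with subcommands `simulate`, `decompose`, `connectivity`, `compare`,
`overlap`, `stability`, `run`.

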