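---
title: "Robust functional connectivity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust functional connectivity: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpsconn)
```

## The problem

Resting-state fMRI yields, per subject, a $T \times J$ matrix of BOLD
signals over $J$ anatomical regions of interest (ROIs). Functional
connectivity is a $J \times J$ matrix of statistical dependence between
those ROI time series, and group comparisons of connectivity (for
example normal controls versus a disease group) are performed edge by
edge. BOLD signals, however, contain scanner- and acquisition-driven
noise and occasional large outliers, which destabilize both the
connectivity estimates and the downstream tests. `lpsconn` implements a
pipeline that addresses this in three stages:

1. a per-ROI **low-rank plus sparse (L+S) decomposition** of the stacked
   subject-by-time matrices, separating common temporal structure from
   sparse idiosyncratic spikes;
2. **connectivity estimation** by seven estimators, including a
   concentration-inequality-based sparse covariance estimator;
3. **group-difference detection** with edgewise two-sample t-tests,
   Benjamini-Hochberg adjustment, an overlap-rate consistency
   statistic and bootstrap stability assessment.

## The L+S decomposition

For each fixed ROI $j$, the subjects' time courses are stacked into an
$N \times T$ matrix $M$ and split by the convex program

$$\min_{L,S}\ \|L\|_* + \lambda\|S\|_1 \quad \text{s.t. } L + S = M,$$

where $\|\cdot\|_*$ is the nuclear norm (sum of singular values) and
$\|\cdot\|_1$ the entrywise $\ell_1$ norm. $L$ captures the low-rank
common structure across subjects, $S$ the sparse individual variability
and outliers. Smaller $\lambda$ buys a lower-rank $L$ at the price of a
denser $S$.

We solve the program with the **inexact augmented Lagrange multiplier**
(ALM) method: per outer iteration one singular-value-thresholding step
for $L$, one soft-thresholding step for $S$, then the multiplier update
$Y \leftarrow Y + \mu(M - L - S)$ and penalty growth
$\mu \leftarrow \min(\rho_\mu \mu,\ \mu_{\max})$. Defaults are the
standard ones for this solver family: $\mu_0 = 1.25/\|M\|_2$,
$\rho_\mu = 1.5$, relative feasibility tolerance $10^{-7}$, at most
1,000 iterations. These are exposed through `solver_settings()`.

Numerical notes:

* The feasibility residual $\|M - L_k - S_k\|_F$ decreases monotonically
  in practice until it reaches roughly $10^{-5}$ relative; below that
  the growing penalty $\mu$ amplifies double-precision rounding and
  nanoscale bumps (order $10^{-8}$) can appear. The test suite asserts
  strict monotonicity above that floor.
* The numerical rank of $L$ counts singular values above
  $\max(N,T)\,\varepsilon\,\sigma_{\max}$ — the standard rank
  tolerance.
* An all-zero input short-circuits to $L = S = 0$.
* Non-convergence within the iteration cap is returned with
  `converged = FALSE`, and `decompose_tensor()` records it per ROI in
  its diagnostics instead of aborting the tensor.

**Default $\lambda$.** When no cross-validation is requested we use
$\lambda = 1/\sqrt{\max(N, T)}$, the universal choice under which exact
recovery of an incoherent low-rank plus sparse pair is guaranteed with
high probability. For the 57-subject, 134-timepoint design this gives
$1/\sqrt{134} \approx 0.086$.

**Cross-validation.** No off-the-shelf CV notion exists for an
unsupervised exact decomposition, so `choose_lambda_cv()` uses entry
masking: per fold, a random 10% of each ROI slice's entries is held
out, the decomposition is solved with the equality constraint enforced
on observed entries only, and each candidate $\lambda$ is scored by the
held-out mean squared error of $L$. Because the planted spikes and the
covariance-driven signal are zero-mean given the low-rank structure,
the held-out risk is minimized near the $\lambda$ whose full-data $L$
is closest to the planted truth — this is exercised directly in the
test suite on a generated tensor. One pooled $\lambda$ is selected for
all ROI slices; whether to pool or select per ROI is genuinely open,
and we pool because the downstream comparison treats all ROIs
symmetrically (a per-slice mode would be a one-line loop over
`solve_lps`).

Both groups are stacked jointly before decomposing (the common features
are assumed shared across groups); `by_group = TRUE` decomposes each
group separately. Time courses enter the decomposition as-is —
demeaning happens later, inside covariance estimation, where it
belongs.

## Connectivity estimators

All estimators start from a subject's $T \times J$ signal matrix $M$
(original BOLD or its low-rank component) and are dispatched by
`estimate_connectivity()`:

| method | construction | default parameter |
|---|---|---|
| `correlation` | $r_{pq} = s_{pq}/(s_{pp}s_{qq})^{1/2}$ from the unbiased sample covariance | — |
| `sparse_correlation` | off-diagonal $r\,\mathbf 1\{|r| > \tau\}$ | $\tau = 0.4$ |
| `partial_correlation` | $\rho_{pq} = -\theta_{pq}/(\theta_{pp}\theta_{qq})^{1/2}$, $\Theta = \hat\Sigma^{-1}$ | — |
| `sparse_partial_correlation` | hard-thresholded partial correlations | $\tau = 0.8$ original, $0.2$ low-rank |
| `glasso_precision` | $\hat\Theta$ maximizing $\log\det\Theta - \mathrm{tr}(S\Theta) - \rho\|\Theta\|_1$ | $\rho = 0.1$ |
| `glasso_partial_correlation` | partial correlations of $\hat\Theta$ | $\rho = 0.1$ |
| `sparse_covariance` | concentration-inequality thresholding, below | $\alpha = 0.35$ |

Hard thresholding uses the strict indicator ($|r| > \tau$ survives), so
$\tau = 1$ yields the identity and $\tau = 0$ leaves the matrix
unchanged. When $T \le J$ the sample covariance is singular and partial
correlations fall back to the Moore-Penrose pseudo-inverse with a
warning (a trace-scaled $10^{-6}$ ridge is available as
`singular_policy = "ridge"`).

The graphical lasso is solved by block coordinate descent over columns
(each column update a lasso regression solved by coordinate descent),
with the penalty on **all** entries including the diagonal; hence the
closed form $\hat\theta_{ii} = 1/(s_{ii} + \rho)$ in the fully
penalized regime, which the tests exploit, alongside an independent
proximal-gradient maximizer that agrees with the block solver to
$10^{-6}$ in objective.

### The concentration-inequality sparse covariance estimator

The estimator treats sparsity as a confidence-set search rather than a
tuning problem: starting from the sample correlation matrix $R$, it
applies a generalized thresholding operator $s_\lambda$ (soft by
default, hard selectable; both satisfy the defining properties of never
growing magnitude, vanishing at or below $\lambda$, and moving a value
by at most $\lambda$) and seeks the **largest** $\lambda$ such that
$d(s_\lambda(R), R) \le r_\alpha$, where $r_\alpha$ is the radius of a
$(1-\alpha)$ confidence ball. $\lambda$ is located by a dyadic
bisection from $1/2$ with $k_{\max} = 10$ halving steps; we return the
largest *feasible* $\lambda$ visited, so the final estimate always lies
inside the confidence set (the raw bisection endpoint can overshoot by
one step). The tests verify the bisection against exhaustive search on
a $2^{-10}$ grid. The estimate is rescaled to covariance by
$\hat\Sigma_{sp} = \hat\Sigma_{diag}^{1/2} s_\lambda(R)
\hat\Sigma_{diag}^{1/2}$, and correlation-scaling it for connectivity
preserves the zero pattern exactly.

Two quantities are deliberately concrete design choices:

* **Distance $d$**: the operator norm, computed as the spectral norm of
  the difference (largest singular value); the maximum absolute entry
  is available via `metric = "maxabs"`.
* **Radius $r_\alpha$**: the theory ties $r_\alpha$ to a concentration
  inequality $P(d(\Sigma, S) \ge E\,d + r) \le e^{-\psi(r)}$ with
  $\psi$ increasing and $\psi(0) = 0$, but no closed form is fixed
  here. We calibrate $r_\alpha$ by a seeded bootstrap: resample
  timepoints with replacement (`n_boot = 200`), measure $d$ between
  each resampled correlation matrix and the observed one, and take the
  empirical $(1-\alpha)$ quantile, with the observed matrix's zero
  distance included so $r_\alpha \to 0$ as $\alpha \to 1$. This keeps
  the printed monotonicity (smaller $\alpha$, larger radius) and makes
  the whole estimator self-contained and deterministic given a seed.
  It is a Monte-Carlo surrogate for an analytic radius, and is labelled
  as such wherever it surfaces.

Because the radius calibration resamples the data, `concentration_radius()`
takes the $T \times J$ signal matrix itself rather than a covariance
summary — a covariance alone cannot be resampled over timepoints.

## Group-difference testing

Per upper-triangle edge $(p, q)$, the per-subject connectivity values
of the two groups are compared with a two-sample t-test. **Welch** is
the default (group sizes 33 and 24 are unequal and there is no reason
to assume equal variances); the pooled-variance variant is selectable.
Edges with zero variance in both groups — routine after hard
thresholding zeroes an edge for every subject — get $p = 1$ and a flag,
and are never dropped. The p-value matrix is symmetric with a diagonal
of 1, and only the $J(J-1)/2$ upper-triangle edges (6,670 for
$J = 116$) are ever counted.

Benjamini-Hochberg adjustment is always computed alongside the raw
p-values, but the default summaries use the raw values at level 0.05;
`adjusted = TRUE` switches. Both are reported because edgewise
screening at a fixed level and FDR control answer different questions,
and the overlap-rate statistic below is defined on a fixed-level
significant set.

**Overlap rate.** To quantify consistency between the original-signal
and low-rank analyses, let $n_1$ count edges with
$\text{level} > p^{orig} > p^{low}$ and $n_2$ those with
$p^{orig} \le p^{low} < \text{level}$. Ties $p^{orig} = p^{low}$ below
the level are counted once (in $n_2$) so that identical analyses give
rate 1. The default denominator is the number of edges significant
under the original analysis, which makes the rate a fraction in
$[0, 1]$ (the intersection of the two significant sets over the
original one); dividing by the literal count of nonzero upper-triangle
p-values is selectable via `denominator = "nonzero_original"`, but with
continuous p-values that denominator is essentially the total edge
count and the resulting rates are not comparable across levels.

**Bootstrap stability.** `bootstrap_stability()` resamples subjects
with replacement within each group at its own size (default
$B = 50$), recomputes per-subject connectivity — re-running the L+S
decomposition per replicate when the low-rank branch is assessed, since
the resampled stack changes the decomposition (a fast approximate mode
reuses the original decomposition) — reruns the edgewise tests, and
reports the per-replicate percentages of significant connections and
their sample variance. All resampling indices are drawn up front from
the seed, so reports are bit-reproducible.

## The synthetic generator

`generate_group_tensor()` provides ground truth for every downstream
stage. Each subject's $T \times J$ matrix is the superposition of

1. a zero-mean multivariate normal ROI signal with the subject's group
   covariance (independent across timepoints),
2. a per-ROI rank-$r$ temporal component shared across subjects
   (subject loadings common to all ROIs times a per-ROI temporal
   basis, so each stacked $N \times T$ ROI slice has a planted rank-$r$
   part),
3. i.i.d. Gaussian noise, and
4. sparse spikes of fixed magnitude and random sign at uniformly drawn
   tensor positions.

Group covariances are built as a block compound-symmetric baseline
(unit variances, correlation 0.3 in blocks of 4 ROIs) for group 0;
group 1 adds $\pm$`effect_size` on `n_diff_edges` randomly chosen ROI
pairs. If the requested effect would make the matrix indefinite the
generator refuses with instructions to lower the effect, rather than
projecting to the positive-definite cone — projection would perturb
edges outside the planted set and break the exact ground-truth
contract that recovery tests rely on.

Defaults mirror the target study design: groups of 33 and 24 subjects,
$T = 134$ timepoints, $J = 116$ ROIs, rank 5 common structure, 5%
outliers of magnitude 10 signal s.d., noise s.d. 0.1, 20 differing
edges of effect 0.2. Random signs on spikes avoid mean shifts that
would confound the t-tests.

What the generator does *not* emulate: hemodynamic response functions,
temporal autocorrelation of BOLD noise, scanner drift, physiological
noise spectra, or spatial voxel structure. Passing tests therefore
demonstrate the pipeline's statistical and numerical correctness under
an idealized signal model, not robustness to every artifact of real
fMRI.

## Problem sizes used in validation

The test-suite and acceptance computations run at desk scale, chosen to
exercise every contract while keeping the suite quick: recovery suites
use the full $57 \times 134$ slice geometry over 10 seeds; calibration
studies use $J = 20$ ROIs with the full 33/24 subject split over 20
replicates; bisection-versus-grid comparisons use 10-ROI, $T = 200$
instances over 50 seeds; bootstrap checks use $B = 50$ at $J = 20$.

## Known limitations

* The bootstrap-calibrated $r_\alpha$ is a surrogate for the analytic
  concentration radius; absolute sparsity levels at a given $\alpha$
  will differ from implementations using a closed-form $\psi$, though
  the monotone behaviour in $\alpha$ is preserved.
* The entry-masking CV for $\lambda$ is a matrix-completion criterion;
  with very high spike densities (well beyond 5%) the held-out risk
  becomes spike-dominated and flattens.
* Partial correlations with $T \le J$ rest on a pseudo-inverse; they
  are reported, but rank deficiency makes them fragile and the
  graphical-lasso route is preferable there.
* `glasso()` uses dense linear algebra per column; it is comfortable at
  $J \approx 116$ but not intended for thousands of ROIs.

## A minimal session

```{r example, eval = FALSE}
g <- generate_group_tensor(synthetic_config(
  n_group0 = 33, n_group1 = 24, n_time = 134, n_roi = 20,
  n_diff_edges = 10, effect_size = 0.25, seed = 1))
dir <- tempfile()
manifest <- write_tensor(g$tensor, dir, truth = g$truth)

res <- run_pipeline(pipeline_config(
  manifest, methods = c("correlation", "sparse_correlation",
                        "sparse_covariance"),
  bootstrap_B = 50, seed = 1))
res$percent_table
res$overlap_table
res$top_pairs$correlation.lowrank
```
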