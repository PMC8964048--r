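Package: lpsconn
Title: Robust Functional Brain Connectivity via Low-Rank Plus Sparse
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for robust estimation and group comparison of
    functional brain connectivity from ROI-level BOLD time series.
    Per-ROI low-rank plus sparse (L+S) matrix decomposition by inexact
    augmented Lagrange multipliers separates common temporal structure
    from sparse outliers; connectivity matrices are then constructed by
    seven estimators (Pearson and partial correlation with optional hard
    thresholding, graphical lasso precision and partial correlation, and
    a concentration-inequality-based sparse covariance estimator).
    Group differences are detected with edgewise two-sample t-tests,
    Benjamini-Hochberg adjustment, an overlap-rate consistency statistic
    between original-signal and low-rank analyses, and bootstrap
    stability of the percentage of significant connections.  A synthetic
    tensor generator with known low-rank structure, sparse spikes and
    group-differing covariance provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
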