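## Pipeline orchestration and file I/O: manifests, per-subject CSVs,
## ROI label tables, the end-to-end run.

#' Packaged AAL-116 ROI label table
#'
#' The standard 116-region Automated Anatomical Labeling parcellation:
#' per ROI, its 1-based atlas index, side-prefixed abbreviation (e.g.
#' \code{L.HIP}), full name and anatomical classification (e.g.
#' \code{Limbic lobe}).
#'
#' @return Data frame with columns \code{index}, \code{abbreviation},
#'   \code{name}, \code{classification}.
#' @export
aal116_labels <- function() {
  read_roi_labels(system.file("extdata", "aal116_labels.csv",
                              package = "lpsconn", mustWork = TRUE))
}

#' Read an ROI label table
#'
#' @param path CSV with columns \code{index}, \code{abbreviation},
#'   \code{classification} (and optionally \code{name}); indices must
#'   be contiguous 1..J and abbreviations unique.
#' @return Validated data frame.
#' @export
read_roi_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "abbreviation", "classification")
  if (!all(need %in% names(df)))
    stop("label table must have columns index, abbreviation, classification")
  if (!identical(as.integer(df$index), seq_len(nrow(df))))
    stop("label indices must be contiguous 1..J")
  if (anyDuplicated(df$abbreviation))
    stop("ROI abbreviations must be unique")
  df
}

#' Write a tensor as per-subject delimited text plus a manifest
#'
#' One CSV per subject (T rows x J columns, header = ROI
#' abbreviations), a \code{manifest.csv} with columns
#' \code{subject_id}, \code{group}, \code{file_path} (relative to the
#' manifest), and, when ground truth is supplied, a
#' \code{truth.json} bundle.
#'
#' @param tensor A \code{\link{roi_tensor}}.
#' @param dir Output directory (created if missing).
#' @param truth Optional truth list from
#'   \code{\link{generate_group_tensor}}.
#' @param prefix Subject file-name prefix.
#' @return Path of the written manifest, invisibly.
#' @export
write_tensor <- function(tensor, dir, truth = NULL, prefix = "subject") {
  stopifnot(inherits(tensor, "roi_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(tensor$values)
  J <- d[3]
  abbr <- if (!is.null(tensor$roi_labels))
    tensor$roi_labels$abbreviation[seq_len(J)] else paste0("ROI", seq_len(J))
  ids <- sprintf("%s%03d", prefix, seq_len(d[1]))
  files <- paste0(ids, ".csv")
  for (i in seq_len(d[1])) {
    m <- tensor$values[i, , , drop = FALSE][1, , ]
    ## %.17g round-trips doubles exactly through text
    ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    con <- file(file.path(dir, files[i]), "w")
    writeLines(paste(abbr, collapse = ","), con)
    writeLines(apply(ch, 1, paste, collapse = ","), con)
    close(con)
  }
  manifest <- data.frame(subject_id = ids,
                         group = as.character(tensor$group_labels),
                         file_path = files)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(sigma0 = truth$sigma0, sigma1 = truth$sigma1,
           diff_edge_set = truth$diff_edge_set,
           group_labels = as.character(truth$group_labels),
           seed = truth$seed),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(mpath)
}

#' Assemble a tensor from a subject manifest
#'
#' Reads a manifest (columns \code{subject_id}, \code{group},
#' \code{file_path}, paths relative to the manifest location), loads
#' each subject's T x J delimited-text time series, validates that all
#' subjects share the same T and J, and assembles the
#' \code{\link{roi_tensor}}.  Dimension mismatches are hard errors
#' naming the offending file.
#'
#' @param path Manifest CSV path.
#' @param roi_labels Optional label table attached to the tensor.
#' @return A \code{\link{roi_tensor}}.
#' @export
read_subject_manifest <- function(path, roi_labels = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "file_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns subject_id, group, file_path")
  base <- dirname(path)
  mats <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$file_path[i])
    if (!file.exists(f)) stop("subject file not found: ", f)
    m <- as.matrix(utils::read.csv(f, check.names = FALSE))
    if (!is.numeric(m))
      stop("non-numeric values in subject file: ", f)
    mats[[i]] <- m
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stop(sprintf("dimension mismatch in %s: %d x %d, expected %d x %d",
                 man$file_path[bad], dims[1, bad], dims[2, bad],
                 dims[1, 1], dims[2, 1]))
  }
  arr <- array(0, dim = c(nrow(man), dims[1, 1], dims[2, 1]))
  for (i in seq_len(nrow(man))) arr[i, , ] <- mats[[i]]
  roi_tensor(arr, man$group, roi_labels)
}

#' Pipeline configuration
#'
#' Validated bundle of everything \code{\link{run_pipeline}} needs.
#'
#' @param manifest Path to the subject manifest.
#' @param labels Optional ROI label table path (defaults to the
#'   packaged AAL-116 table when J = 116).
#' @param lambda_ Numeric sparsity weight, \code{"cv"} (cross-validate
#'   over \code{lambda_grid}), or \code{NULL} for the default
#'   \eqn{1/\sqrt{\max(N,T)}}.
#' @param lambda_grid Grid used when \code{lambda_ = "cv"}.
#' @param methods Character vector of connectivity method tags.
#' @param method_params Named list (per method) of parameter lists;
#'   \code{tau_lowrank} overrides \code{tau} on the low-rank branch.
#' @param variant t-test variant.
#' @param level Significance level.
#' @param adjusted Summarize BH-adjusted p-values instead of raw.
#' @param bootstrap_B Bootstrap replicates (0 disables bootstrap).
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(manifest, labels = NULL,
                            lambda_ = NULL, lambda_grid = NULL,
                            methods = c("correlation",
                                        "sparse_correlation",
                                        "sparse_covariance"),
                            method_params = list(),
                            variant = "welch", level = 0.05,
                            adjusted = FALSE,
                            bootstrap_B = 0L,
                            out_dir = tempfile("lpsconn_run_"),
                            seed = 1L) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  if (!is.null(labels) && !file.exists(labels))
    stop("label table not found: ", labels)
  if (length(methods) == 0) stop("at least one method must be requested")
  valid <- c("correlation", "sparse_correlation", "partial_correlation",
             "sparse_partial_correlation", "glasso_precision",
             "glasso_partial_correlation", "sparse_covariance")
  if (!all(methods %in% valid))
    stop("unknown method(s): ", paste(setdiff(methods, valid), collapse = ", "))
  if (is.character(lambda_) && lambda_ == "cv" && is.null(lambda_grid))
    stop("`lambda_grid` is required when lambda_ = \"cv\"")
  stop_if_not_scalar_prob(level, "level")
  structure(list(manifest = manifest, labels = labels,
                 lambda_ = lambda_, lambda_grid = lambda_grid,
                 methods = methods, method_params = method_params,
                 variant = variant, level = level,
                 adjusted = isTRUE(adjusted),
                 bootstrap_B = as.integer(bootstrap_B),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

## Default per-branch thresholds (overridable via method_params):
## tau 0.4 for correlation-type on both branches, tau 0.8 / 0.2 for
## partial correlations on original / low-rank signals.
default_method_params <- function(method, branch) {
  switch(method,
    sparse_correlation = list(tau = 0.4),
    sparse_partial_correlation =
      list(tau = if (branch == "original") 0.8 else 0.2),
    glasso_precision = list(rho = 0.1),
    glasso_partial_correlation = list(rho = 0.1),
    sparse_covariance = list(alpha = 0.35),
    list())
}

#' Run the full robust-connectivity pipeline
#'
#' Reads the subject tensor, runs the per-ROI L+S decomposition, builds
#' per-subject connectivity matrices for every requested method on both
#' the original-signal and low-rank branches, performs the edgewise
#' group tests (raw and BH-adjusted), and writes summaries: percentage
#' of significant connections per method per branch, top-10 ROI pairs,
#' overlap rates between branches, optional bootstrap stability, and a
#' machine-readable run record.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The results bundle (also written under \code{out_dir}),
#'   invisibly: \code{percent_table}, \code{overlap_table},
#'   \code{top_pairs}, \code{pvalues}, \code{bootstrap},
#'   \code{decomposition}, \code{lambda}, \code{run_record}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  labels <- if (!is.null(config$labels)) read_roi_labels(config$labels)
            else NULL
  tensor <- read_subject_manifest(config$manifest, labels)
  d <- dim(tensor$values)
  if (is.null(labels) && d[3] == 116) labels <- aal116_labels()

  ## -- decomposition stage -------------------------------------------
  lambda_ <- config$lambda_
  cv_table <- NULL
  if (is.character(lambda_) && lambda_ == "cv") {
    cv <- choose_lambda_cv(tensor, config$lambda_grid, seed = config$seed)
    lambda_ <- cv$best_lambda
    cv_table <- cv$score_table
  }
  if (is.null(lambda_)) lambda_ <- 1 / sqrt(max(d[1], d[2]))
  dec <- decompose_tensor(tensor, lambda_)

  glev <- levels(tensor$group_labels)
  if (length(glev) != 2) stop("exactly two groups are required")
  idx0 <- which(tensor$group_labels == glev[1])
  idx1 <- which(tensor$group_labels == glev[2])

  branches <- list(original = tensor$values,
                   lowrank = dec$L_tensor$values)
  percent_rows <- list()
  overlap_rows <- list()
  pvalues <- list()
  top_pairs <- list()
  for (method in config$methods) {
    pmats <- list()
    for (branch in names(branches)) {
      pars <- utils::modifyList(default_method_params(method, branch),
                                config$method_params[[method]] %||% list())
      pars$tau_lowrank <- NULL
      if (branch == "lowrank" &&
          !is.null(config$method_params[[method]]$tau_lowrank))
        pars$tau <- config$method_params[[method]]$tau_lowrank
      arr <- branches[[branch]]
      conn <- lapply(seq_len(d[1]), function(i)
        do.call(estimate_connectivity,
                c(list(M = arr[i, , , drop = FALSE][1, , ],
                       method = method), pars)))
      P_raw <- edgewise_ttest(conn[idx0], conn[idx1], config$variant)
      P_adj <- bh_adjust(P_raw)
      P_use <- if (config$adjusted) P_adj else P_raw
      pmats[[branch]] <- P_use
      pvalues[[paste(method, branch, sep = ".")]] <-
        list(raw = P_raw, adjusted = P_adj)
      s <- percent_significant(P_use, config$level)
      percent_rows[[length(percent_rows) + 1]] <-
        data.frame(method = method, signal = branch,
                   percent = s$percent, n_significant = s$n_significant,
                   total_edges = s$total_edges)
      top_pairs[[paste(method, branch, sep = ".")]] <-
        top_significant_pairs(P_use, labels, k = 10L)
      utils::write.csv(P_use$values,
                       file.path(config$out_dir,
                                 sprintf("pvalues_%s_%s.csv", method, branch)),
                       row.names = FALSE)
    }
    o <- overlap_rate(pmats$original, pmats$lowrank, config$level)
    overlap_rows[[length(overlap_rows) + 1]] <-
      data.frame(method = method, n1 = o$n1, n2 = o$n2,
                 denominator = o$denominator, rate = o$rate)
  }
  percent_table <- do.call(rbind, percent_rows)
  overlap_table <- do.call(rbind, overlap_rows)

  boot <- NULL
  if (config$bootstrap_B >= 2) {
    boot <- lapply(config$methods, function(method)
      bootstrap_stability(tensor, method,
                          params = config$method_params[[method]] %||% list(),
                          B = config$bootstrap_B, level = config$level,
                          seed = config$seed, variant = config$variant))
    names(boot) <- config$methods
  }

  run_record <- list(
    package_version = as.character(utils::packageVersion("lpsconn")),
    seed = config$seed, lambda = lambda_,
    methods = config$methods, level = config$level,
    adjusted = config$adjusted, variant = config$variant,
    dims = list(n_subjects = d[1], n_time = d[2], n_roi = d[3],
                groups = as.list(table(tensor$group_labels))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  jsonlite::write_json(
    list(percent_significant = percent_table, overlap = overlap_table,
         run_record = run_record),
    file.path(config$out_dir, "summary.json"),
    digits = NA, auto_unbox = TRUE, dataframe = "rows")
  utils::write.csv(percent_table,
                   file.path(config$out_dir, "percent_significant.csv"),
                   row.names = FALSE)
  utils::write.csv(overlap_table,
                   file.path(config$out_dir, "overlap_rates.csv"),
                   row.names = FALSE)

  invisible(list(percent_table = percent_table,
                 overlap_table = overlap_table,
                 top_pairs = top_pairs, pvalues = pvalues,
                 bootstrap = boot, decomposition = dec,
                 lambda = lambda_, cv_table = cv_table,
                 run_record = run_record, labels = labels,
                 out_dir = config$out_dir))
}
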