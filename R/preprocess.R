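# Metabolomics preprocessing: missingness filtering, iterative
# tree-ensemble imputation, log2 + Pareto scaling, perfect-correlate
# removal, and Hotelling-T2 PCA outlier detection.

#' Remove metabolites with excessive missingness
#'
#' Drops metabolite columns whose missing fraction is strictly greater than
#' `threshold` (a column missing in exactly 30.0% of samples is retained at
#' the default threshold).
#'
#' @param matrix samples x metabolites numeric matrix, `NA` = missing.
#' @param threshold missingness fraction in (0, 1); default 0.30.
#' @return list with `matrix` (retained columns, order preserved) and
#'   `excluded` (dropped metabolite names).
#' @export
filter_missingness <- function(matrix, threshold = 0.30) {
  stopifnot(nrow(matrix) > 0, ncol(matrix) > 0,
            threshold > 0, threshold < 1)
  frac <- colMeans(is.na(matrix))
  drop <- frac > threshold
  if (all(drop)) stop("all metabolites exceed the missingness threshold")
  list(matrix = matrix[, !drop, drop = FALSE],
       excluded = colnames(matrix)[drop])
}

#' Impute missing concentrations with an iterative tree ensemble
#'
#' Random-forest regression imputation in the missForest style: missing
#' cells start at per-metabolite medians, then metabolites are cycled in
#' order of increasing missingness, each regressed on all others with a
#' random forest and its missing cells replaced by the forest predictions,
#' until the relative change of the imputed cells falls below `tol` or
#' `max_iter` cycles. Observed cells are never modified.
#'
#' @param matrix samples x metabolites matrix with `NA` for missing; every
#'   column needs at least two observed values.
#' @param seed integer seed (mandatory; forests and cycling are seeded).
#' @param num_trees trees per forest.
#' @param max_iter maximum improvement cycles.
#' @param tol relative-change stopping tolerance.
#' @return completed numeric matrix.
#' @export
impute_missing <- function(matrix, seed, num_trees = 100, max_iter = 10,
                           tol = 1e-4) {
  if (missing(seed)) stop("seed is mandatory")
  miss <- is.na(matrix)
  if (!any(miss)) return(matrix)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0))
    stop("fully missing metabolite(s): ",
         paste(colnames(matrix)[n_obs == 0], collapse = ", "),
         " (filter before imputing)")
  if (any(n_obs < 2))
    stop("metabolite(s) with fewer than 2 observed values")
  set.seed(as.integer(seed))
  X <- matrix
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[miss[, j], j] <- med[j]

  target_cols <- order(colMeans(miss))
  target_cols <- target_cols[colSums(miss)[target_cols] > 0]
  prev <- X[miss]
  for (iter in seq_len(max_iter)) {
    for (j in target_cols) {
      obs <- !miss[, j]
      df <- data.frame(..y = X[obs, j], X[obs, -j, drop = FALSE],
                       check.names = FALSE)
      fit <- ranger::ranger(
        dependent.variable.name = "..y", data = df,
        num.trees = num_trees, seed = sample.int(.Machine$integer.max, 1),
        num.threads = 1)
      newdata <- data.frame(X[!obs, -j, drop = FALSE], check.names = FALSE)
      X[!obs, j] <- stats::predict(fit, data = newdata,
                                   num.threads = 1)$predictions
    }
    cur <- X[miss]
    delta <- sum((cur - prev)^2) / max(sum(cur^2), .Machine$double.eps)
    prev <- cur
    if (delta < tol) break
  }
  X
}

#' Log2 transform and Pareto-scale a concentration matrix
#'
#' Per cell `x -> log2(x)`, then per metabolite column
#' `x' = (x - mean) / sqrt(sd)` with mean and sample standard deviation of
#' the log2 values. Pareto scaling leaves each column with variance equal
#' to its pre-scaling standard deviation, damping (rather than erasing, as
#' autoscaling would) the leverage of high-variance metabolites. Constant
#' columns are returned as all zeros with a warning.
#'
#' @param matrix strictly positive samples x metabolites matrix (no
#'   missing values).
#' @return scaled matrix with attributes `center` (log2 means) and
#'   `scale` (sqrt of log2 sds).
#' @export
log2_pareto <- function(matrix) {
  if (anyNA(matrix)) stop("matrix contains missing values; impute first")
  bad <- which(matrix <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("nonpositive concentration at [",
         rownames(matrix)[bad[1, 1]] %||% bad[1, 1], ", ",
         colnames(matrix)[bad[1, 2]] %||% bad[1, 2], "]")
  L <- log2(matrix)
  mu <- colMeans(L)
  sdv <- apply(L, 2, stats::sd)
  const <- sdv < .Machine$double.eps^0.5
  if (any(const)) {
    warning("constant column(s) mapped to zero: ",
            paste(colnames(matrix)[const], collapse = ", "))
    sdv[const] <- Inf  # centred values are 0 already; any divisor works
  }
  out <- sweep(sweep(L, 2, mu), 2, sqrt(sdv), `/`)
  out[, const] <- 0
  attr(out, "center") <- mu
  attr(out, "scale") <- sqrt(sdv)
  out
}

#' Drop perfectly correlated metabolites
#'
#' For every metabolite pair with `|Pearson r| >= r_threshold` the later
#' column (in input order) is dropped, mirroring the practice of removing a
#' metabolite that tracks another 1:1.
#'
#' @param matrix imputed samples x metabolites matrix (no missing values).
#' @param r_threshold absolute correlation at or above which a pair counts
#'   as perfect (default 0.999).
#' @return list with `matrix`, `dropped` (column names removed) and
#'   `pairs` (data.frame kept/dropped/r).
#' @export
drop_perfect_correlates <- function(matrix, r_threshold = 0.999) {
  if (anyNA(matrix)) stop("matrix contains missing values; impute first")
  C <- suppressWarnings(stats::cor(matrix))
  C[is.na(C)] <- 0
  p <- ncol(matrix)
  drop <- logical(p)
  pairs <- list()
  for (j in seq_len(p)) {
    if (drop[j]) next
    hits <- which(abs(C[j, ]) >= r_threshold)
    hits <- hits[hits > j & !drop[hits]]
    for (h in hits) {
      drop[h] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(kept = colnames(matrix)[j],
                   dropped = colnames(matrix)[h],
                   r = C[j, h], stringsAsFactors = FALSE)
    }
  }
  list(matrix = matrix[, !drop, drop = FALSE],
       dropped = colnames(matrix)[drop],
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(kept = character(0), dropped = character(0),
                    r = numeric(0)))
}

#' Detect multivariate outliers in PCA score space
#'
#' Fits a PCA and flags samples whose Hotelling-T2 statistic on the
#' (PC1, PC2) or the (PC1, PC3) score plane exceeds the `(1 - alpha)`
#' quantile of the classical F-based reference distribution
#' `2 (n - 1)(n + 1) / (n (n - 2)) * F(2, n - 2)` — the T2 ellipse drawn in
#' standard PCA score plots.
#'
#' @param matrix normalized samples x metabolites matrix, >= 3 samples.
#' @param alpha significance level per score plane (default 0.05).
#' @return list with `outliers` (sample ids flagged), `statistics`
#'   (data.frame of per-sample T2 on both planes and the limit).
#' @export
detect_outliers_pca <- function(matrix, alpha = 0.05) {
  n <- nrow(matrix)
  stopifnot(n >= 3)
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  usable <- which(pc$sdev > max(pc$sdev) * 1e-8)
  k <- length(usable)
  if (k < 3) warning("fewer than 3 informative principal components; ",
                     "using the ", k, " available")
  t2_lim <- function(a) a * (n - 1) * (n + 1) / (n * (n - a)) *
    stats::qf(1 - alpha, a, n - a)
  t2 <- function(idx) {
    rowSums(pc$x[, idx, drop = FALSE]^2 %*%
              diag(1 / pc$sdev[idx]^2, length(idx)))
  }
  planes <- list(intersect(c(1, 2), usable), intersect(c(1, 3), usable))
  planes <- unique(Filter(length, planes))
  flag <- rep(FALSE, n)
  lim <- NA_real_
  stats_list <- lapply(planes, function(pl) {
    s <- t2(pl)
    lim_pl <- t2_lim(length(pl))
    flag <<- flag | s > lim_pl
    s
  })
  lim <- t2_lim(length(planes[[1]]))
  t2_12 <- stats_list[[1]]
  t2_13 <- if (length(stats_list) > 1) stats_list[[2]]
           else rep(NA_real_, n)
  ids <- rownames(matrix) %||% as.character(seq_len(n))
  list(outliers = ids[flag],
       statistics = data.frame(sample_id = ids, t2_pc12 = t2_12,
                               t2_pc13 = t2_13, limit = lim,
                               flagged = flag, stringsAsFactors = FALSE))
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: missingness filter -> tree-ensemble imputation -> log2 +
#' Pareto scaling -> perfect-correlate removal -> PCA outlier detection ->
#' outlier removal (single pass, no refit loop). Returns both the
#' normalized outlier-free matrix used for clustering and the imputed raw
#' matrix (pre-normalization) used for fold-change computation.
#'
#' @param matrix raw samples x metabolites matrix, `NA` = missing.
#' @param seed integer seed for the imputation forests.
#' @param missing_threshold,r_threshold,alpha stage parameters (see the
#'   stage functions).
#' @return list with `normalized` (outlier-free scaled matrix), `imputed`
#'   (raw-scale imputed matrix, all samples, filtered columns), and
#'   `report` (a `PreprocessReport`).
#' @export
preprocess_concentrations <- function(matrix, seed,
                                      missing_threshold = 0.30,
                                      r_threshold = 0.999,
                                      alpha = 0.05) {
  f <- filter_missingness(matrix, missing_threshold)
  imputed <- impute_missing(f$matrix, seed = seed)
  scaled <- log2_pareto(imputed)
  dc <- drop_perfect_correlates(scaled, r_threshold)
  out <- detect_outliers_pca(dc$matrix, alpha)
  keep <- setdiff(rownames(dc$matrix), out$outliers)
  report <- structure(list(
    excluded_metabolites = f$excluded,
    dropped_correlates = dc$dropped,
    correlate_pairs = dc$pairs,
    imputed_cells = sum(is.na(f$matrix)),
    outliers = out$outliers,
    outlier_statistics = out$statistics,
    parameters = list(missing_threshold = missing_threshold,
                      r_threshold = r_threshold, alpha = alpha,
                      seed = seed)
  ), class = "PreprocessReport")
  list(normalized = dc$matrix[keep, , drop = FALSE],
       imputed = imputed,
       report = report)
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat("<PreprocessReport>\n",
      "  excluded (> ", x$parameters$missing_threshold * 100, "% missing): ",
      length(x$excluded_metabolites), "\n",
      "  imputed cells: ", x$imputed_cells, "\n",
      "  perfect correlates dropped: ",
      paste(x$dropped_correlates, collapse = ", "), "\n",
      "  outliers: ", paste(x$outliers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a preprocessing report to JSON
#'
#' @param report a `PreprocessReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
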