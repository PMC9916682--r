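# Phenotype discovery: complete-linkage hierarchical clustering and PLS-DA
# variable-importance ranking.

#' Hierarchical clustering of samples into phenotypes
#'
#' Agglomerative clustering with Euclidean distance and complete linkage,
#' cut to exactly `k` clusters. The merge order is deterministic for a
#' given input: on equal merge heights the pair with the lowest indices is
#' merged first (the tie-break of the underlying agglomeration routine).
#' Cluster labels are arbitrary integers 1..k; see
#' [assign_phenotype_letters()] for the biology-anchored A-D labelling.
#'
#' @param matrix preprocessed samples x metabolites matrix.
#' @param k number of clusters, `2 <= k <= n_samples` (k = 1 allowed and
#'   returns a single cluster).
#' @return a `PhenotypeAssignment`: list with `labels` (named integer
#'   vector), `tree` (the `hclust` object), `k`.
#' @export
hier_cluster <- function(matrix, k = 4) {
  n <- nrow(matrix)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  tree <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                        method = "complete")
  labels <- stats::cutree(tree, k = k)
  names(labels) <- rownames(matrix)
  structure(list(labels = labels, tree = tree, k = k),
            class = "PhenotypeAssignment")
}

#' @export
print.PhenotypeAssignment <- function(x, ...) {
  cat("<PhenotypeAssignment> k = ", x$k, "; sizes: ",
      paste(table(x$labels), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Map cluster numbers to phenotype letters A-D
#'
#' The letters encode biology, not size: the cluster with the highest mean
#' of the marker metabolite (succinate by default) is labelled `D`; the
#' remaining clusters are lettered `A`, `B`, `C`, ... in the order their
#' first leaf appears in the dendrogram.
#'
#' @param assignment a `PhenotypeAssignment`.
#' @param matrix the matrix that was clustered (columns must include
#'   `marker`).
#' @param marker metabolite column anchoring phenotype `D`.
#' @return named character vector of letters, one per sample.
#' @export
assign_phenotype_letters <- function(assignment, matrix,
                                     marker = "succinate") {
  stopifnot(inherits(assignment, "PhenotypeAssignment"))
  if (!marker %in% colnames(matrix))
    stop("marker metabolite '", marker, "' not in matrix")
  labels <- assignment$labels
  ks <- sort(unique(labels))
  marker_mean <- vapply(ks, function(g)
    mean(matrix[labels == g, marker]), numeric(1))
  d_cluster <- ks[which.max(marker_mean)]
  leaf_order <- assignment$tree$order
  first_leaf <- vapply(ks, function(g)
    min(match(which(labels == g), leaf_order)), numeric(1))
  rest <- ks[ks != d_cluster][order(first_leaf[ks != d_cluster])]
  letter <- stats::setNames(rep(NA_character_, length(ks)), ks)
  letter[as.character(rest)] <- LETTERS[seq_along(rest)]
  letter[as.character(d_cluster)] <- LETTERS[length(ks)]
  out <- letter[as.character(labels)]
  names(out) <- names(labels)
  out
}

#' PLS-DA variable importance in projection
#'
#' Fits a PLS-DA (partial least squares against the one-hot class matrix)
#' and returns the standard VIP score per metabolite, aggregated over
#' `n_components` with the weighted-sum-of-squares formula; the mean of the
#' squared VIP scores equals 1 by construction. Metabolites are returned
#' sorted by descending VIP.
#'
#' @param matrix preprocessed samples x metabolites matrix.
#' @param labels class label per sample (>= 2 classes, no singleton class).
#' @param n_components number of PLS components (default 2).
#' @return a `VipTable` data.frame with columns `metabolite`, `vip`,
#'   `rank`; attribute `n_components`.
#' @export
plsda_vip <- function(matrix, labels, n_components = 2) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("class(es) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  fit <- mixOmics::plsda(matrix, labels, ncomp = n_components)
  v <- mixOmics::vip(fit)
  vip <- v[, ncol(v)]
  out <- data.frame(metabolite = names(vip), vip = unname(vip),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$vip), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_components") <- n_components
  class(out) <- c("VipTable", "data.frame")
  out
}

#' Render the phenotype heatmap and its ordered matrix
#'
#' Writes a clustered heatmap image and, as the testable artifact, the
#' underlying matrix with rows reordered to the dendrogram leaf order
#' (columns clustered the same way) as CSV.
#'
#' @param matrix preprocessed samples x metabolites matrix.
#' @param assignment the `PhenotypeAssignment` for the samples of `matrix`.
#' @param path output path for the image (`.png`); the ordered matrix goes
#'   to the same path with extension `.csv`.
#' @return named vector with the files written, invisibly.
#' @export
render_phenotype_heatmap <- function(matrix, assignment, path) {
  stopifnot(inherits(assignment, "PhenotypeAssignment"))
  if (!setequal(rownames(matrix), names(assignment$labels)))
    stop("assignment does not cover the matrix samples")
  leaf <- assignment$tree$order
  ordered <- matrix[leaf, , drop = FALSE]
  col_tree <- stats::hclust(stats::dist(t(matrix)), method = "complete")
  ordered <- ordered[, col_tree$order, drop = FALSE]
  csv_path <- sub("\\.[^.]+$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  utils::write.csv(
    data.frame(sample_id = rownames(ordered),
               phenotype = assignment$labels[rownames(ordered)],
               ordered, check.names = FALSE),
    csv_path, row.names = FALSE)
  ann <- data.frame(cluster = factor(assignment$labels))
  rownames(ann) <- names(assignment$labels)
  grDevices::png(path, width = 1200, height = 900, res = 120)
  pheatmap::pheatmap(matrix,
                     clustering_distance_rows = "euclidean",
                     clustering_distance_cols = "euclidean",
                     clustering_method = "complete",
                     annotation_row = ann,
                     show_rownames = nrow(matrix) <= 60,
                     main = "Plasma metabolic phenotypes")
  grDevices::dev.off()
  invisible(c(image = path, csv = csv_path))
}

#' Serialize a linkage tree to JSON
#'
#' @param assignment a `PhenotypeAssignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_linkage_tree <- function(assignment, path) {
  tr <- assignment$tree
  jsonlite::write_json(
    list(merge = apply(tr$merge, 1, identity, simplify = FALSE),
         height = tr$height, order = tr$order,
         labels = tr$labels, k = assignment$k),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
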