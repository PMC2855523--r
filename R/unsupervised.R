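#' Center and scale samples for multidimensional scaling
#'
#' Each sample (column) is centered by its mean and standardized by the
#' Euclidean norm of the centered vector, so every output sample has zero
#' mean and unit norm. The transform is idempotent.
#'
#' @param mat numeric matrix, assays x samples, no missing values (filter
#'   to complete assays first, e.g. via [complete_assays()]).
#' @return matrix of the same shape with unit-norm, zero-mean columns.
#' @export
center_scale_samples <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat))
    stop("center_scale_samples requires a complete matrix; ",
         "drop masked assays first (see complete_assays)")
  if (nrow(mat) < 2) stop("each sample needs at least 2 values")
  ctr <- sweep(mat, 2, colMeans(mat))
  nrm <- sqrt(colSums(ctr^2))
  if (any(nrm == 0)) stop("constant sample cannot be scaled")
  sweep(ctr, 2, nrm, "/")
}

#' Restrict a matrix to assays observed in every sample
#'
#' @param mat assays x samples matrix with `NA` for masked cells.
#' @return the subset of rows without missing values.
#' @export
complete_assays <- function(mat) {
  mat[stats::complete.cases(mat), , drop = FALSE]
}

#' MDS embedding of samples (Euclidean, equivalent to PCA)
#'
#' Embeds samples in the space of the first `k` principal components of
#' the centered-and-scaled sample profiles. With Euclidean distances this
#' classical multidimensional scaling is exactly a principal component
#' analysis: pairwise distances in the full component space equal the
#' input distances.
#'
#' @param mat assays x samples matrix; masked (`NA`) assays are dropped
#'   row-wise, then samples are centered/scaled via
#'   [center_scale_samples()] unless `scale = FALSE`.
#' @param k number of components to return (default 3).
#' @param scale apply the center-and-scale transform first (default TRUE).
#' @return object of class `mds_embedding`: list with `sample_ids`,
#'   `coordinates` (samples x k), `explained_variance` (fraction per
#'   returned component), `sdev` (all singular values / sqrt(n - 1)).
#' @export
mds_embed <- function(mat, k = 3, scale = TRUE) {
  mat <- complete_assays(as.matrix(mat))
  if (ncol(mat) < 4) stop("need at least 4 samples")
  x <- if (scale) center_scale_samples(mat) else mat
  X <- t(x)                              # samples x assays
  # principal components over samples: remove the mean sample profile, so
  # the axes are the classical-MDS axes of the Euclidean distances
  X <- sweep(X, 2, colMeans(X))
  if (k > ncol(X) || k > nrow(X)) {
    warning("fewer dimensions than requested components; truncating")
    k <- min(k, ncol(X), nrow(X))
  }
  sv <- svd(X)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  varfrac <- sv$d^2 / sum(sv$d^2)
  coords <- scores[, seq_len(k), drop = FALSE]
  rownames(coords) <- colnames(mat)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(sample_ids = colnames(mat), coordinates = coords,
         explained_variance = varfrac[seq_len(k)], sdev = sv$d,
         scores = scores),
    class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("MDS/PCA embedding of", length(x$sample_ids), "samples;",
      "variance explained:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write an embedding as a TSV table
#'
#' @param emb an `mds_embedding`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  out <- data.frame(sample = emb$sample_ids, emb$coordinates,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal: Eisen-style centered-correlation distance with a defined
# maximum (2) for constant profiles
.correlation_dist <- function(mat) {
  cc <- suppressWarnings(stats::cor(t(mat)))
  cc[!is.finite(cc)] <- -1        # constant profile: maximal distance
  d <- stats::as.dist(1 - cc)
  attr(d, "constant_rows") <- which(apply(mat, 1, stats::sd) == 0)
  d
}

#' Hierarchical clustering of assays and/or samples
#'
#' Agglomerative clustering in the Eisen heat-map convention: centered
#' Pearson correlation distance (`1 - r`) with average linkage by default.
#' Input is typically log2 fold-change values or MammU6-normalized CT.
#' Constant profiles, for which the correlation is undefined, are assigned
#' the maximal distance and flagged.
#'
#' @param mat numeric matrix, assays x samples; rows with `NA` are dropped.
#' @param axis cluster `"assays"` (rows), `"samples"` (columns) or
#'   `"both"`.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return object of class `cluster_tree`: list with `assays` and/or
#'   `samples` elements, each an `hclust` object, plus `matrix` (the
#'   clustered data) and `constant_rows`.
#' @export
hierarchical_cluster <- function(mat, axis = c("assays", "samples", "both"),
                                 metric = c("correlation", "euclidean"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  mat <- complete_assays(as.matrix(mat))
  mkdist <- function(m) {
    if (nrow(m) < 2) stop("need at least 2 items on the clustered axis")
    if (metric == "correlation") .correlation_dist(m) else stats::dist(m)
  }
  out <- list(matrix = mat, metric = metric, linkage = linkage,
              constant_rows = integer(0))
  if (axis %in% c("assays", "both")) {
    d <- mkdist(mat)
    out$constant_rows <- attr(d, "constant_rows") %||% integer(0)
    out$assays <- stats::hclust(d, method = linkage)
  }
  if (axis %in% c("samples", "both")) {
    out$samples <- stats::hclust(mkdist(t(mat)), method = linkage)
  }
  structure(out, class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree (", x$metric, "distance,", x$linkage, "linkage):")
  if (!is.null(x$assays)) cat(" assays =", length(x$assays$order))
  if (!is.null(x$samples)) cat(" samples =", length(x$samples$order))
  cat("\n")
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` object (e.g. `tree$samples`).
#' @param path output path.
#' @return `path`, invisibly. Requires the `ape` package.
#' @export
write_dendrogram <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
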