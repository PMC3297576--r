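#' Keep genes expressed above a threshold in every sample
#'
#' The similarity analysis considers only genes with RPKM above the
#' threshold (default 1) in all samples, so that the subsequent log
#' transform is defined everywhere.
#'
#' @param mat Genes x samples matrix of gene RPKM.
#' @param threshold Strict lower bound (gene kept iff RPKM > threshold in
#'   every sample).
#' @return The filtered matrix.
#' @export
expressed_in_all_filter <- function(mat, threshold = 1.0) {
  keep <- apply(mat > threshold, 1L, all)
  if (!any(keep))
    stopf("no gene exceeds RPKM %.3g in all samples; review the threshold",
          threshold)
  mat[keep, , drop = FALSE]
}

#' Power-law normalization of expression values
#'
#' Gene expression follows a Zipf-like power-law distribution; a log10
#' transform linearizes it so that the Pearson correlation is a meaningful
#' similarity. The transform is strictly monotone and requires positive
#' input (guaranteed by [expressed_in_all_filter()] with threshold >= 0).
#'
#' @param x Positive numeric vector or matrix.
#' @return log10 of the input.
#' @export
powerlaw_normalize <- function(x) {
  if (any(x <= 0)) stopf("power-law normalization requires positive values")
  log10(x)
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation in [-1, 1].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors of unequal length")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in at least one vector")
  stats::cor(x, y, method = "pearson")
}

#' Cluster samples by correlation distance
#'
#' Computes all pairwise Pearson correlations between sample expression
#' profiles (already filtered and normalized), and builds a complete-linkage
#' agglomerative dendrogram on the (1 - PCC) distance. With this distance,
#' merge heights lie in [0, 2] and are non-decreasing toward the root. Ties
#' in the agglomeration are resolved by sample order in the input matrix,
#' which is fixed, making the dendrogram reproducible.
#'
#' @param mat Genes x samples matrix of normalized expression.
#' @return List of class `sample_clustering`: `pcc` (samples x samples
#'   correlation matrix), `dist` (1 - PCC, as dist), `hclust` and `phylo`
#'   (ape tree, for Newick export).
#' @export
cluster_samples <- function(mat) {
  if (ncol(mat) < 3L) stopf("need at least 3 samples to cluster")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance sample(s): %s",
          paste(colnames(mat)[sds == 0], collapse = ", "))
  C <- stats::cor(mat, method = "pearson")
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = "complete")
  structure(list(pcc = C, dist = d, hclust = hc,
                 phylo = ape::as.phylo(hc)),
            class = "sample_clustering")
}

#' Full similarity analysis from a gene RPKM matrix
#'
#' Convenience wrapper: RPKM > threshold in-all-samples filter, log10
#' power-law normalization, then [cluster_samples()].
#'
#' @param gene_rpkm Genes x samples RPKM matrix.
#' @param threshold Expression filter threshold.
#' @return A `sample_clustering` (with the filtered, normalized matrix
#'   attached as `matrix`).
#' @export
sample_similarity <- function(gene_rpkm, threshold = 1.0) {
  m <- powerlaw_normalize(expressed_in_all_filter(gene_rpkm, threshold))
  res <- cluster_samples(m)
  res$matrix <- m
  res
}

#' Write a dendrogram in Newick format
#'
#' @param clustering A `sample_clustering`.
#' @param path Output file.
#' @export
write_newick <- function(clustering, path) {
  ape::write.tree(clustering$phylo, file = path)
  invisible(path)
}

#' Pairwise-PCC long table
#'
#' One row per unordered sample pair, the tabular counterpart of the
#' clustering heatmap.
#'
#' @param clustering A `sample_clustering`.
#' @return data.frame with sample_a, sample_b, pcc.
#' @export
pcc_table <- function(clustering) {
  C <- clustering$pcc
  idx <- which(upper.tri(C), arr.ind = TRUE)
  data.frame(sample_a = rownames(C)[idx[, 1L]],
             sample_b = colnames(C)[idx[, 2L]],
             pcc = C[idx],
             stringsAsFactors = FALSE)
}
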