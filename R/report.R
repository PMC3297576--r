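#' Expressed-gene summary
#'
#' Two distinct "expressed" notions coexist in this analysis and are kept
#' separate: a gene is *expressed* when its median RPKM across samples
#' exceeds the threshold (used for candidate-gene reporting), and *detected
#' in a sample* when its RPKM exceeds the threshold in that sample (the
#' per-sample detection whose intersection gives "expressed in all
#' individuals"). Both use a strict `>`.
#'
#' @param gene_rpkm Genes x samples matrix of gene RPKM.
#' @param threshold Expression threshold (default 1 RPKM).
#' @return List: `expressed` (ids with median > threshold), `n_expressed`,
#'   `detected_per_sample` (counts), `median_genes_per_sample` (median of
#'   the per-sample detection counts), `in_all` (ids detected in every
#'   sample), `n_in_all`, `in_some` (detected somewhere but not everywhere),
#'   `n_in_some`.
#' @export
expressed_gene_set <- function(gene_rpkm, threshold = 1.0) {
  if (ncol(gene_rpkm) < 1L) stopf("need at least one sample")
  med <- apply(gene_rpkm, 1L, stats::median)
  detected <- gene_rpkm > threshold
  per_sample <- colSums(detected)
  in_all <- rownames(gene_rpkm)[rowSums(detected) == ncol(gene_rpkm)]
  in_any <- rownames(gene_rpkm)[rowSums(detected) > 0L]
  list(expressed = rownames(gene_rpkm)[med > threshold],
       n_expressed = sum(med > threshold),
       detected_per_sample = per_sample,
       median_genes_per_sample = stats::median(per_sample),
       in_all = in_all,
       n_in_all = length(in_all),
       in_some = setdiff(in_any, in_all),
       n_in_some = length(setdiff(in_any, in_all)))
}

#' Candidate-gene expression report
#'
#' For a list of candidate gene ids (e.g. disease-risk genes from GWAS),
#' reports the median RPKM per condition and whether the gene is expressed
#' (median control RPKM > threshold), plus the summary count and integer
#' percentage of expressed candidates. Ids absent from the annotation are
#' listed separately, not silently dropped.
#'
#' @param candidate_ids Character vector of gene ids.
#' @param gene_rpkm_ctl Genes x samples RPKM matrix, control condition.
#' @param gene_rpkm_cyt Optional matching matrix for the cytokine condition.
#' @param threshold Expression threshold.
#' @return List: `table` (per-candidate rows), `unresolved`, `n_candidates`,
#'   `n_expressed`, `pct_expressed` (nearest-integer percent, NA when no
#'   candidate resolves).
#' @export
candidate_gene_report <- function(candidate_ids, gene_rpkm_ctl,
                                  gene_rpkm_cyt = NULL, threshold = 1.0) {
  candidate_ids <- unique(as.character(candidate_ids))
  resolved <- candidate_ids[candidate_ids %in% rownames(gene_rpkm_ctl)]
  unresolved <- setdiff(candidate_ids, resolved)
  if (length(resolved)) {
    med_ctl <- apply(gene_rpkm_ctl[resolved, , drop = FALSE], 1L,
                     stats::median)
    med_cyt <- if (!is.null(gene_rpkm_cyt))
      apply(gene_rpkm_cyt[resolved, , drop = FALSE], 1L, stats::median)
    else rep(NA_real_, length(resolved))
    tab <- data.frame(gene_id = resolved,
                      median_rpkm_control = unname(med_ctl),
                      median_rpkm_cytokine = unname(med_cyt),
                      expressed = unname(med_ctl > threshold),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(gene_id = character(), median_rpkm_control = numeric(),
                      median_rpkm_cytokine = numeric(), expressed = logical(),
                      stringsAsFactors = FALSE)
  }
  list(table = tab,
       unresolved = unresolved,
       n_candidates = length(candidate_ids),
       n_expressed = sum(tab$expressed),
       pct_expressed = percent_of(sum(tab$expressed), length(candidate_ids)))
}

#' Differential-call summary with reporting arithmetic
#'
#' Condenses a calls table (or explicit counts) into the headline numbers:
#' genes up, down, total modified, and the nearest-integer percentage of
#' the "present" genes that were modified.
#'
#' @param calls Either a calls data.frame from [differential_genes()] or a
#'   named list/vector with `n_up` and `n_down`.
#' @param n_present Number of genes considered present/detected.
#' @return List: `n_up`, `n_down`, `n_modified`, `pct_modified`.
#' @export
de_summary <- function(calls, n_present) {
  if (is.data.frame(calls)) {
    n_up <- sum(calls$call == "up")
    n_down <- sum(calls$call == "down")
  } else {
    n_up <- calls[["n_up"]]; n_down <- calls[["n_down"]]
  }
  list(n_up = n_up, n_down = n_down, n_modified = n_up + n_down,
       pct_modified = percent_of(n_up + n_down, n_present))
}
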