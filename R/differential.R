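# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]].
# Sum of all hypergeometric outcome probabilities not exceeding the observed
# one (with the customary 1 + 1e-7 relative slack against ties lost to
# floating point). Vector-free scalar core used by both callers.
fisher_p_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  pobs <- probs[support == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Fisher exact test for a gene between paired conditions
#'
#' Tests the 2x2 table of reads mapped to the gene versus reads mapped to
#' all other genes, cytokine condition versus control, for one donor pair.
#' The p-value is the two-sided Fisher exact probability; the direction is
#' the sign of the difference in gene read proportions (not derived from the
#' test itself), so exactly equal proportions give direction 0.
#'
#' @param gene_reads_cyt,total_reads_cyt Gene and total mapped reads in the
#'   cytokine sample.
#' @param gene_reads_ctl,total_reads_ctl Same for the control sample.
#' @return List with `p` and `direction_sign` (-1, 0, +1).
#' @export
fisher_gene_pair <- function(gene_reads_cyt, total_reads_cyt,
                             gene_reads_ctl, total_reads_ctl) {
  if (gene_reads_cyt > total_reads_cyt || gene_reads_ctl > total_reads_ctl)
    stopf("gene reads exceed total reads")
  if (total_reads_cyt <= 0 || total_reads_ctl <= 0)
    stopf("totals must be positive")
  if (gene_reads_cyt < 0 || gene_reads_ctl < 0)
    stopf("gene reads must be non-negative")
  a <- gene_reads_cyt; b <- total_reads_cyt - gene_reads_cyt
  c <- gene_reads_ctl; d <- total_reads_ctl - gene_reads_ctl
  list(p = fisher_p_2x2(a, b, c, d),
       direction_sign = sign(a / (a + b) - c / (c + d)))
}

#' Fisher exact test for a transcript within its gene
#'
#' Tests deconvolved reads assigned to one transcript versus reads assigned
#' to all other transcripts of the same gene, cytokine versus control.
#' Assigned reads must already be rounded to integers (see
#' [round_assigned_reads()]). For single-transcript genes the test is
#' undefined and the unit is skipped upstream.
#'
#' @param tx_reads_cyt,other_reads_cyt Transcript and other-transcript reads
#'   in the cytokine sample.
#' @param tx_reads_ctl,other_reads_ctl Same for control.
#' @return List with `p` and `direction_sign`.
#' @export
fisher_transcript_pair <- function(tx_reads_cyt, other_reads_cyt,
                                   tx_reads_ctl, other_reads_ctl) {
  if (any(c(tx_reads_cyt, other_reads_cyt, tx_reads_ctl, other_reads_ctl) < 0))
    stopf("read counts must be non-negative")
  tot_cyt <- tx_reads_cyt + other_reads_cyt
  tot_ctl <- tx_reads_ctl + other_reads_ctl
  dir <- if (tot_cyt == 0 || tot_ctl == 0) 0 else
    sign(tx_reads_cyt / tot_cyt - tx_reads_ctl / tot_ctl)
  list(p = fisher_p_2x2(tx_reads_cyt, other_reads_cyt,
                        tx_reads_ctl, other_reads_ctl),
       direction_sign = dir)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment within one family. In this
#' pipeline the family is deliberately the per-unit set of sample-pair
#' p-values (size = number of donor pairs), not the genome-wide set: each
#' gene's five pairwise tests are treated as the independent tests being
#' corrected. This per-unit family is unusual among RNA-seq methods but is
#' the procedure this pipeline reproduces; [differential_genes()] exposes a
#' `bh_scope` switch for the genome-wide alternative.
#'
#' @param p Numeric vector of p-values in [0,1].
#' @return Adjusted p-values, order-preserving with the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Log2 expression change between condition RPKM sums
#'
#' `log2(cyt/ctl)` when both sums are positive. When one side is zero the
#' ratio is undefined; a documented +/- `cap` sentinel (default 20, i.e. a
#' million-fold change, beyond any observable ratio at these library sizes)
#' is returned instead of inventing a pseudocount. `NA` when both are zero.
#'
#' @param rpkm_sum_cyt,rpkm_sum_ctl Gene RPKM sums (>= 0).
#' @param cap Sentinel magnitude for zero-denominator/numerator cases.
#' @return Signed log2 ratio, +/- cap sentinel, or NA.
#' @export
log2_expression_change <- function(rpkm_sum_cyt, rpkm_sum_ctl, cap = 20) {
  if (rpkm_sum_cyt < 0 || rpkm_sum_ctl < 0) stopf("RPKM sums must be >= 0")
  if (rpkm_sum_cyt == 0 && rpkm_sum_ctl == 0) return(NA_real_)
  if (rpkm_sum_ctl == 0) return(cap)
  if (rpkm_sum_cyt == 0) return(-cap)
  log2(rpkm_sum_cyt / rpkm_sum_ctl)
}

#' Splice-index difference between conditions
#'
#' @param si_cyt,si_ctl Splice indices in [0,1]; NA (undefined, e.g. a gene
#'   with zero RPKM in one condition) propagates.
#' @return `si_cyt - si_ctl` or NA.
#' @export
delta_splice_index <- function(si_cyt, si_ctl) {
  ifelse(is.na(si_cyt) | is.na(si_ctl), NA_real_, si_cyt - si_ctl)
}

#' Round deconvolved reads for the transcript-level Fisher test
#'
#' Deconvolution yields real-valued assigned reads; the Fisher table needs
#' integers. Rounding is half-to-even (base R `round`), applied at this
#' single documented point.
#'
#' @param x Real assigned reads.
#' @return Integer-valued numeric.
#' @export
round_assigned_reads <- function(x) round(x)

#' Directional replication-consistency call
#'
#' A unit (gene or transcript) is called changed only if its adjusted
#' p-value is below `alpha` with the same direction sign in at least
#' `min_consistent` of the sample pairs, and in no pair significant in the
#' opposite direction. Pairs with exactly equal proportions (direction 0)
#' never contribute to either count.
#'
#' @param p_adj Vector of BH-adjusted p-values, one per sample pair.
#' @param direction_sign Matching vector of -1/0/+1 direction signs.
#' @param alpha Significance level on the adjusted p-values.
#' @param min_consistent Minimum number of same-direction significant pairs.
#' @return List with `call` ("up", "down" or "unchanged"),
#'   `n_significant_up`, `n_significant_down`.
#' @export
call_unit <- function(p_adj, direction_sign, alpha = 0.05,
                      min_consistent = 4L) {
  if (length(p_adj) != length(direction_sign))
    stopf("p_adj and direction_sign lengths differ")
  if (length(p_adj) < min_consistent)
    stopf("fewer sample pairs (%d) than min_consistent (%d)",
          length(p_adj), min_consistent)
  sig <- !is.na(p_adj) & p_adj < alpha
  n_up <- sum(sig & direction_sign > 0)
  n_down <- sum(sig & direction_sign < 0)
  call <- if (n_up >= min_consistent && n_down == 0L) "up"
  else if (n_down >= min_consistent && n_up == 0L) "down"
  else "unchanged"
  list(call = call, n_significant_up = n_up, n_significant_down = n_down)
}

# shared caller over a units x pairs structure of tests
consistency_calls <- function(unit_ids, pair_ids, p_raw, sign, effect,
                              alpha, min_consistent, bh_scope) {
  n_units <- length(unit_ids); n_pairs <- length(pair_ids)
  p_adj <- matrix(NA_real_, n_units, n_pairs)
  if (bh_scope == "per_unit") {
    for (i in seq_len(n_units)) p_adj[i, ] <- bh_adjust(p_raw[i, ])
  } else {
    p_adj[] <- bh_adjust(as.vector(p_raw))
  }
  calls <- character(n_units); nup <- integer(n_units); ndn <- integer(n_units)
  med_eff <- rep(NA_real_, n_units)
  for (i in seq_len(n_units)) {
    cl <- call_unit(p_adj[i, ], sign[i, ], alpha, min_consistent)
    calls[i] <- cl$call; nup[i] <- cl$n_significant_up
    ndn[i] <- cl$n_significant_down
    sig <- !is.na(p_adj[i, ]) & p_adj[i, ] < alpha & sign[i, ] != 0
    if (any(sig)) med_eff[i] <- stats::median(effect[i, sig], na.rm = TRUE)
  }
  # per-pair direction is "none" unless the pair is significant at alpha
  # (after BH) with unequal proportions
  sig_v <- !is.na(as.vector(p_adj)) & as.vector(p_adj) < alpha
  dir_v <- ifelse(sig_v & as.vector(sign) > 0, "up",
                  ifelse(sig_v & as.vector(sign) < 0, "down", "none"))
  per_pair <- data.frame(
    unit_id = rep(unit_ids, times = n_pairs),
    pair_id = rep(pair_ids, each = n_units),
    p_raw = as.vector(p_raw), p_adj = as.vector(p_adj),
    effect = as.vector(effect),
    direction = dir_v,
    stringsAsFactors = FALSE)
  list(per_pair = per_pair,
       calls = data.frame(unit_id = unit_ids, call = calls,
                          n_significant_up = nup, n_significant_down = ndn,
                          median_significant_effect = med_eff,
                          stringsAsFactors = FALSE))
}

# donor pairing table from a samples data.frame
donor_pairs <- function(samples) {
  ctl <- samples[samples$condition == "control", ]
  cyt <- samples[samples$condition == "cytokine", ]
  donors <- sort(intersect(ctl$donor_id, cyt$donor_id))
  if (!length(donors)) stopf("no paired control/cytokine donors in samples")
  data.frame(donor_id = donors,
             control = ctl$sample_id[match(donors, ctl$donor_id)],
             cytokine = cyt$sample_id[match(donors, cyt$donor_id)],
             stringsAsFactors = FALSE)
}

#' Call cytokine-modified genes
#'
#' For every gene and donor pair, performs the Fisher exact test of gene
#' reads versus all-other-gene reads (cytokine vs control), adjusts the
#' p-values by Benjamini-Hochberg within the per-gene family of sample
#' pairs, computes the log2 ratio of gene RPKM sums, and applies the
#' directional consistency rule.
#'
#' @param quant An `islet_quant` from [quantify_dataset()].
#' @param alpha Significance level (default 0.05 on adjusted p-values).
#' @param min_consistent Minimum same-direction significant pairs (default 4).
#' @param log2_cap Sentinel for zero-RPKM log2 ratios.
#' @param bh_scope `"per_unit"` (each gene's pairs form the BH family, the
#'   procedure reproduced here) or `"genome_wide"` (one family across all
#'   genes and pairs).
#' @return List with `per_pair` (long table of per-gene per-pair results)
#'   and `calls` (per-gene final call with significant-pair counts and the
#'   median significant log2 change).
#' @export
differential_genes <- function(quant, alpha = 0.05, min_consistent = 4L,
                               log2_cap = 20,
                               bh_scope = c("per_unit", "genome_wide")) {
  bh_scope <- match.arg(bh_scope)
  pairs <- donor_pairs(quant$samples)
  genes <- rownames(quant$gene_reads)
  n <- length(genes); np <- nrow(pairs)
  p_raw <- matrix(NA_real_, n, np)
  sgn <- matrix(0, n, np)
  eff <- matrix(NA_real_, n, np)
  for (j in seq_len(np)) {
    s_ctl <- pairs$control[j]; s_cyt <- pairs$cytokine[j]
    tot_ctl <- quant$totals[[s_ctl]]; tot_cyt <- quant$totals[[s_cyt]]
    g_ctl <- quant$gene_reads[, s_ctl]; g_cyt <- quant$gene_reads[, s_cyt]
    for (i in seq_len(n)) {
      ft <- fisher_gene_pair(g_cyt[i], tot_cyt, g_ctl[i], tot_ctl)
      p_raw[i, j] <- ft$p; sgn[i, j] <- ft$direction_sign
      eff[i, j] <- log2_expression_change(quant$gene_rpkm[i, s_cyt],
                                          quant$gene_rpkm[i, s_ctl],
                                          cap = log2_cap)
    }
  }
  consistency_calls(genes, pairs$donor_id, p_raw, sgn, eff,
                    alpha, min_consistent, bh_scope)
}

#' Call cytokine-modified spliceforms
#'
#' For every transcript of a multi-isoform gene and every donor pair,
#' performs the Fisher exact test of rounded deconvolved reads assigned to
#' the transcript versus reads assigned to the other transcripts of the same
#' gene (cytokine vs control), adjusts per transcript across pairs by
#' Benjamini-Hochberg, computes the splice-index difference, and applies the
#' directional consistency rule. Transcripts of single-isoform genes are
#' excluded (the within-gene test is undefined) and reported in `skipped`.
#'
#' @inheritParams differential_genes
#' @return List with `per_pair`, `calls` (effect = median significant
#'   splice-index difference) and `skipped` (transcripts of single-isoform
#'   genes).
#' @export
differential_transcripts <- function(quant, alpha = 0.05, min_consistent = 4L,
                                     bh_scope = c("per_unit", "genome_wide")) {
  bh_scope <- match.arg(bh_scope)
  pairs <- donor_pairs(quant$samples)
  gene_of_tx <- quant$gene_of_tx
  multi_genes <- names(which(table(gene_of_tx) >= 2L))
  keep <- gene_of_tx %in% multi_genes
  tx <- names(gene_of_tx)[keep]
  skipped <- names(gene_of_tx)[!keep]
  reads <- round_assigned_reads(quant$tx_reads[tx, , drop = FALSE])
  gene_tot <- rowsum(reads, gene_of_tx[tx])
  n <- length(tx); np <- nrow(pairs)
  p_raw <- matrix(NA_real_, n, np); sgn <- matrix(0, n, np)
  eff <- matrix(NA_real_, n, np)
  for (j in seq_len(np)) {
    s_ctl <- pairs$control[j]; s_cyt <- pairs$cytokine[j]
    for (i in seq_len(n)) {
      g <- gene_of_tx[[tx[i]]]
      a <- reads[i, s_cyt]; b <- gene_tot[g, s_cyt] - a
      cc <- reads[i, s_ctl]; d <- gene_tot[g, s_ctl] - cc
      ft <- fisher_transcript_pair(a, b, cc, d)
      p_raw[i, j] <- ft$p; sgn[i, j] <- ft$direction_sign
      eff[i, j] <- delta_splice_index(quant$tx_si[tx[i], s_cyt],
                                      quant$tx_si[tx[i], s_ctl])
    }
  }
  res <- consistency_calls(tx, pairs$donor_id, p_raw, sgn, eff,
                           alpha, min_consistent, bh_scope)
  res$skipped <- skipped
  res
}

#' Tissue-enrichment calls for islet genes against one background tissue
#'
#' Applies the same machinery as the cytokine comparison, but compares each
#' untreated (control) islet sample against a single background tissue
#' sample: Fisher exact test on gene reads vs all-other-gene reads, BH
#' adjustment within the per-gene family of islet samples, direction from
#' proportion differences, and the directional consistency rule. The
#' reported effect is the median of the significant log2 RPKM differences.
#'
#' @param quant An `islet_quant`.
#' @param background_sample Sample id of the background tissue.
#' @param islet_samples Sample ids of the islet samples to compare
#'   (defaults to all control islet samples).
#' @inheritParams differential_genes
#' @return List with `per_pair` and `calls`; calls are `"up"` (islet
#'   enriched), `"down"` (islet depleted) or `"unchanged"` (ns).
#' @export
tissue_enrichment <- function(quant, background_sample,
                              islet_samples = NULL,
                              alpha = 0.05, min_consistent = 4L,
                              log2_cap = 20) {
  samples <- quant$samples
  if (is.null(islet_samples))
    islet_samples <- samples$sample_id[samples$condition == "control"]
  if (length(islet_samples) < min_consistent)
    stopf("fewer islet samples (%d) than min_consistent (%d)",
          length(islet_samples), min_consistent)
  if (!background_sample %in% colnames(quant$gene_reads))
    stopf("unknown background sample '%s'", background_sample)
  genes <- rownames(quant$gene_reads)
  n <- length(genes); np <- length(islet_samples)
  p_raw <- matrix(NA_real_, n, np); sgn <- matrix(0, n, np)
  eff <- matrix(NA_real_, n, np)
  tot_bg <- quant$totals[[background_sample]]
  g_bg <- quant$gene_reads[, background_sample]
  for (j in seq_len(np)) {
    s <- islet_samples[j]
    tot_is <- quant$totals[[s]]
    g_is <- quant$gene_reads[, s]
    for (i in seq_len(n)) {
      ft <- fisher_gene_pair(g_is[i], tot_is, g_bg[i], tot_bg)
      p_raw[i, j] <- ft$p; sgn[i, j] <- ft$direction_sign
      eff[i, j] <- log2_expression_change(quant$gene_rpkm[i, s],
                                          quant$gene_rpkm[i, background_sample],
                                          cap = log2_cap)
    }
  }
  consistency_calls(genes, islet_samples, p_raw, sgn, eff,
                    alpha, min_consistent, "per_unit")
}
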