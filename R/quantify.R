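# Non-negative least squares with a robust fallback chain. The Lawson-Hanson
# active-set solver in pracma can exhaust its iteration budget on
# ill-conditioned designs; in that case the exact optimum is recovered by
# enumerating active sets (feasible for the isoform counts of real gene
# models). Columns are scaled to unit norm first to improve conditioning.
nnls_solve <- function(A, y) {
  scl <- sqrt(colSums(A^2))
  scl[scl == 0] <- 1
  As <- sweep(A, 2L, scl, "/")
  x <- tryCatch(pracma::lsqnonneg(As, y)$x, error = function(e) NULL)
  if (is.null(x)) {
    k <- ncol(As)
    if (k > 20L)
      stopf("NNLS failed on a %d-transcript gene", k)
    best <- list(obj = sum(y^2), x = numeric(k))
    for (bits in seq_len(2^k - 1L)) {
      S <- which(bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0)
      Asub <- As[, S, drop = FALSE]
      xs <- tryCatch(qr.solve(crossprod(Asub), crossprod(Asub, y)),
                     error = function(e) NULL)
      if (is.null(xs) || any(xs < 0)) next
      obj <- sum((Asub %*% xs - y)^2)
      if (obj < best$obj - 1e-12) {
        xx <- numeric(k); xx[S] <- as.numeric(xs)
        best <- list(obj = obj, x = xx)
      }
    }
    x <- best$x
  }
  x / scl
}

#' Deconvolve segment counts into per-transcript abundances
#'
#' Reads observed on exonic segments shared by several transcripts are
#' assigned to individual transcripts by solving the constrained linear
#' system `min ||A theta - c||^2, theta >= 0`, where `A[s, t]` equals the
#' segment length when transcript `t` is a member of segment `s` and zero
#' otherwise, and `c` is the vector of segment counts. Non-negativity is
#' physically required (abundances are reads per base); least squares is the
#' minimal optimizing reading of a linear observation model.
#'
#' Genes whose design matrix is rank-deficient are not identifiable at the
#' transcript level; they are quantified with the minimum-norm optimum
#' (obtained via a vanishing ridge augmentation) and flagged, keeping
#' gene-level read totals valid.
#'
#' @param gene A `GeneModel`.
#' @param segments Segment table for this gene (rows of
#'   [build_all_segments()] with matching `gene_id`).
#' @param counts Numeric vector of segment counts, in segment-table order
#'   (or named by segment_id).
#' @return List with `theta` (abundance, reads per base, per transcript),
#'   `assigned_reads` (`theta * length_bp`), `residual` (objective at the
#'   optimum) and `unidentifiable` flag.
#' @export
deconvolve_gene <- function(gene, segments, counts) {
  stopifnot(inherits(gene, "GeneModel"))
  tx_ids <- names(gene$transcripts)
  if (!is.null(names(counts))) counts <- counts[segments$segment_id]
  if (length(counts) != nrow(segments))
    stopf("gene '%s': %d counts for %d segments", gene$gene_id,
          length(counts), nrow(segments))
  if (any(counts < 0)) stopf("gene '%s': negative counts", gene$gene_id)
  tx_len <- vapply(gene$transcripts, `[[`, 0, "length_bp")

  A <- matrix(0, nrow = nrow(segments), ncol = length(tx_ids),
              dimnames = list(segments$segment_id, tx_ids))
  for (i in seq_len(nrow(segments)))
    A[i, segments$members[[i]]] <- segments$length[i]

  unident <- qr(A)$rank < length(tx_ids)
  if (sum(counts) == 0) {
    theta <- stats::setNames(numeric(length(tx_ids)), tx_ids)
    return(list(theta = theta, assigned_reads = theta, residual = 0,
                unidentifiable = unident))
  }
  if (unident) {
    # vanishing ridge selects the minimum-norm point of the optimal face
    eps <- 1e-6 * max(A)
    theta <- nnls_solve(rbind(A, diag(eps, ncol(A))),
                        c(counts, numeric(ncol(A))))
  } else {
    theta <- nnls_solve(A, as.numeric(counts))
  }
  residual <- sum((A %*% theta - counts)^2)
  names(theta) <- tx_ids
  list(theta = theta,
       assigned_reads = theta * tx_len,
       residual = residual,
       unidentifiable = unident)
}

#' Reads per kilobase per million mapped reads
#'
#' @param assigned_reads Reads assigned to the feature (may be fractional
#'   after deconvolution).
#' @param length_bp Feature length in base pairs (> 0).
#' @param total_mapped_reads Library size: total reads mapped to annotated
#'   segments in the sample (> 0).
#' @return `assigned_reads / ((length_bp/1000) * (total_mapped_reads/1e6))`.
#' @export
#' @examples
#' rpkm(200, 1000, 2e6) # 100
rpkm <- function(assigned_reads, length_bp, total_mapped_reads) {
  if (any(length_bp <= 0)) stopf("length_bp must be positive")
  if (any(total_mapped_reads <= 0)) stopf("total_mapped_reads must be positive")
  if (any(assigned_reads < 0)) stopf("assigned_reads must be non-negative")
  assigned_reads / ((length_bp / 1000) * (total_mapped_reads / 1e6))
}

#' Splice indices from transcript RPKMs
#'
#' The splice index of a transcript is the proportion of its RPKM in the sum
#' of the RPKMs of all transcripts of the same gene. Undefined (NA) when the
#' gene RPKM sum is zero.
#'
#' @param tx_rpkm Numeric vector of transcript RPKMs for one gene.
#' @return Vector of proportions summing to 1, or all-NA when undefined.
#' @export
splice_index <- function(tx_rpkm) {
  total <- sum(tx_rpkm)
  if (total == 0) return(rep(NA_real_, length(tx_rpkm)))
  tx_rpkm / total
}

#' Quantify one sample
#'
#' Runs [deconvolve_gene()] for every gene and derives RPKM and splice
#' indices.
#'
#' @param annotation A `GeneAnnotation`.
#' @param segments Segment table from [build_all_segments()].
#' @param counts Named numeric vector of segment counts for the sample.
#' @param total_mapped_reads Library size; defaults to `sum(counts)` (the
#'   per-sample total over all annotated segments).
#' @return data.frame: gene_id, transcript_id, length_bp, assigned_reads,
#'   rpkm, splice_index, unidentifiable.
#' @export
quantify_sample <- function(annotation, segments, counts,
                            total_mapped_reads = sum(counts)) {
  seg_by_gene <- split(seq_len(nrow(segments)), segments$gene_id)
  res <- lapply(annotation, function(g) {
    idx <- seg_by_gene[[g$gene_id]]
    seg <- segments[idx, , drop = FALSE]
    dec <- deconvolve_gene(g, seg, counts[seg$segment_id])
    len <- vapply(g$transcripts, `[[`, 0, "length_bp")
    rk <- rpkm(dec$assigned_reads, len, total_mapped_reads)
    data.frame(gene_id = g$gene_id,
               transcript_id = names(g$transcripts),
               length_bp = len,
               assigned_reads = dec$assigned_reads,
               rpkm = rk,
               splice_index = splice_index(rk),
               unidentifiable = dec$unidentifiable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Quantify all samples of a dataset
#'
#' @param dataset An `islet_sim` (or any list with `annotation`, `segments`,
#'   `counts` matrix and `samples` data.frame).
#' @return List of class `islet_quant`: `transcript` (long data.frame with a
#'   sample_id column), matrices `tx_reads`, `tx_rpkm`, `tx_si` (transcripts
#'   x samples), `gene_rpkm` and `gene_reads` (genes x samples; gene reads
#'   are the integer sums of observed segment counts per gene), `samples`
#'   and `totals` (per-sample mapped totals used as RPKM denominators).
#' @export
quantify_dataset <- function(dataset) {
  counts <- dataset$counts
  segments <- dataset$segments
  totals <- colSums(counts)
  per_sample <- lapply(colnames(counts), function(s) {
    q <- quantify_sample(dataset$annotation, segments, counts[, s],
                         total_mapped_reads = totals[[s]])
    q$sample_id <- s
    q
  })
  long <- do.call(rbind, per_sample)
  tx_ids <- per_sample[[1L]]$transcript_id
  gene_of_tx <- per_sample[[1L]]$gene_id
  mat <- function(col) {
    m <- vapply(per_sample, function(q) q[[col]], numeric(length(tx_ids)))
    dimnames(m) <- list(tx_ids, colnames(counts))
    m
  }
  tx_reads <- mat("assigned_reads")
  tx_rpkm <- mat("rpkm")
  tx_si <- mat("splice_index")
  gene_rpkm <- rowsum(tx_rpkm, gene_of_tx)
  gene_reads <- rowsum(counts, segments$gene_id)
  structure(list(transcript = long,
                 tx_reads = tx_reads, tx_rpkm = tx_rpkm, tx_si = tx_si,
                 gene_of_tx = stats::setNames(gene_of_tx, tx_ids),
                 gene_rpkm = gene_rpkm, gene_reads = gene_reads,
                 samples = dataset$samples, totals = totals),
            class = "islet_quant")
}
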