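#' Construct a transcript model
#'
#' A transcript is an ordered set of exon intervals on one chromosome and
#' strand. Coordinates are 0-based half-open throughout the package; GTF
#' input/output converts at the boundary. Overlapping or book-ended exons
#' within one transcript are merged with a warning (annotation dialects
#' sometimes emit them split).
#'
#' @param transcript_id,gene_id Identifiers.
#' @param exons Two-column matrix of `start`, `end` (0-based half-open).
#' @return An object of class `Transcript` with fields `transcript_id`,
#'   `gene_id`, `exons` (sorted, non-overlapping) and `length_bp`.
#' @export
new_transcript <- function(transcript_id, gene_id, exons) {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stopf("transcript '%s' has no exons", transcript_id)
  if (any(exons[, 2L] <= exons[, 1L]))
    stopf("transcript '%s' has an empty or inverted exon", transcript_id)
  exons <- exons[order(exons[, 1L], exons[, 2L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    warnf("transcript '%s': overlapping exons merged", transcript_id)
    ir <- IRanges::reduce(IRanges::IRanges(exons[, 1L] + 1L, exons[, 2L]))
    exons <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         exons = exons,
         length_bp = sum(exons[, 2L] - exons[, 1L])),
    class = "Transcript")
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome,strand Shared location of all transcripts.
#' @param transcripts List of [new_transcript()] objects.
#' @return Object of class `GeneModel`.
#' @export
new_gene_model <- function(gene_id, chromosome, strand, transcripts) {
  if (length(transcripts) == 0L) stopf("gene '%s' has no transcripts", gene_id)
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids))
    stopf("gene '%s': duplicated transcript ids", gene_id)
  gids <- vapply(transcripts, `[[`, "", "gene_id")
  if (!all(gids == gene_id))
    stopf("gene '%s': transcript with foreign gene_id", gene_id)
  if (!strand %in% c("+", "-")) stopf("gene '%s': invalid strand", gene_id)
  names(transcripts) <- ids
  structure(
    list(gene_id = as.character(gene_id),
         chromosome = as.character(chromosome),
         strand = strand,
         transcripts = transcripts),
    class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s), %d transcript(s): %s\n",
              x$gene_id, x$chromosome, x$strand, length(x$transcripts),
              paste(names(x$transcripts), collapse = ", ")))
  invisible(x)
}

#' Parse transcript annotation from a GTF file
#'
#' Reads exon features (only exon features are required) and assembles one
#' [new_gene_model()] per `gene_id`. GTF coordinates (1-based inclusive) are
#' converted to the package-internal 0-based half-open convention. Genes are
#' modelled independently: transcripts of different genes that overlap
#' genomically do not share reads downstream.
#'
#' @param path Path to a GTF file whose exon lines carry `gene_id` and
#'   `transcript_id` attributes.
#' @return Named list of `GeneModel` objects (class `GeneAnnotation`).
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stopf("GTF parse error in '%s': %s",
                                           path, conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (!"type" %in% colnames(md)) stopf("GTF '%s' has no feature type column", path)
  ex <- gr[md$type == "exon"]
  if (length(ex) == 0L) stopf("GTF '%s' contains no exon features", path)
  md <- S4Vectors::mcols(ex)
  for (attr in c("gene_id", "transcript_id")) {
    if (!attr %in% colnames(md) || anyNA(md[[attr]])) {
      bad <- if (attr %in% colnames(md)) which(is.na(md[[attr]]))[1L] else 1L
      stopf("GTF '%s': exon feature %d lacks the %s attribute", path, bad, attr)
    }
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    stringsAsFactors = FALSE)

  genes <- lapply(split(df, df$gene_id), function(g) {
    txs <- lapply(split(g, g$transcript_id), function(tx) {
      if (length(unique(tx$chrom)) > 1L || length(unique(tx$strand)) > 1L)
        stopf("transcript '%s' spans multiple chromosomes or strands",
              tx$transcript_id[1L])
      new_transcript(tx$transcript_id[1L], tx$gene_id[1L],
                     cbind(tx$start, tx$end))
    })
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L)
      stopf("gene '%s' spans multiple chromosomes or strands", g$gene_id[1L])
    new_gene_model(g$gene_id[1L], g$chrom[1L], g$strand[1L], txs)
  })
  structure(genes, class = "GeneAnnotation")
}

#' Project a gene model onto maximal exonic segments
#'
#' Cuts the union of all exons of all transcripts at every exon boundary,
#' yielding the maximal intervals with constant transcript membership. These
#' segments are the observation units for read counting and deconvolution:
#' a read falling in a segment is compatible with exactly the member
#' transcripts.
#'
#' @param gene A `GeneModel`.
#' @return data.frame with columns `segment_id`, `gene_id`, `start`, `end`
#'   (0-based half-open), `length`, and list-column `members` (character
#'   vectors of transcript ids covering the segment).
#' @export
build_segments <- function(gene) {
  stopifnot(inherits(gene, "GeneModel"))
  tx_ids <- names(gene$transcripts)
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  n_ex <- vapply(gene$transcripts, function(t) nrow(t$exons), 0L)
  all_ir <- IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L])  # 1-based for IRanges
  seg <- IRanges::disjoin(all_ir)
  hits <- IRanges::findOverlaps(seg, all_ir, type = "within")
  tx_of_exon <- rep(tx_ids, n_ex)
  members <- split(tx_of_exon[S4Vectors::subjectHits(hits)],
                   factor(S4Vectors::queryHits(hits), levels = seq_along(seg)))
  members <- lapply(members, function(m) sort(unique(m)))
  o <- order(IRanges::start(seg))
  seg <- seg[o]; members <- members[o]
  out <- data.frame(
    segment_id = sprintf("%s:seg%03d", gene$gene_id, seq_along(seg)),
    gene_id = gene$gene_id,
    start = IRanges::start(seg) - 1L,
    end = IRanges::end(seg),
    length = IRanges::width(seg),
    stringsAsFactors = FALSE)
  out$members <- unname(members)
  out
}

#' Build segments for a whole annotation
#'
#' @param annotation A `GeneAnnotation` (list of `GeneModel`).
#' @return Row-bound segment table over all genes (see [build_segments()]).
#' @export
build_all_segments <- function(annotation) {
  res <- do.call(rbind, lapply(annotation, build_segments))
  rownames(res) <- res$segment_id
  res
}

#' Export segments as BED
#'
#' BED is 0-based half-open, matching the internal convention; the `name`
#' field carries `gene_id|member1,member2,...`.
#'
#' @param segments Segment table from [build_all_segments()].
#' @param path Output file.
#' @param chromosomes Named character vector mapping gene_id to chromosome
#'   (taken from the annotation).
#' @export
write_segments_bed <- function(segments, path, chromosomes) {
  bed <- data.frame(
    chrom = unname(chromosomes[segments$gene_id]),
    start = segments$start,
    end = segments$end,
    name = paste0(segments$gene_id, "|",
                  vapply(segments$members, paste, "", collapse = ",")),
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write annotation to GTF
#'
#' Emits one exon feature per exon with `gene_id` and `transcript_id`
#' attributes, converting back to GTF 1-based inclusive coordinates. The
#' output carries no timestamp so that pipeline reruns are byte-identical.
#'
#' @param annotation A `GeneAnnotation`.
#' @param path Output file.
#' @export
write_gtf <- function(annotation, path) {
  rows <- lapply(annotation, function(g) {
    do.call(rbind, lapply(g$transcripts, function(tx) {
      data.frame(chrom = g$chromosome, start = tx$exons[, 1L] + 1L,
                 end = tx$exons[, 2L], strand = g$strand,
                 gene_id = g$gene_id, transcript_id = tx$transcript_id,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    source = "isletseq", type = "exon",
    gene_id = df$gene_id, transcript_id = df$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

# exon-union length of a gene (bp)
gene_union_length <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L]))))
}
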