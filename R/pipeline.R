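#' Pipeline run configuration
#'
#' @param out_dir Output directory for all tables and the manifest.
#' @param sim A [sim_config()] describing the synthetic dataset to generate,
#'   or NULL when reading counts from files.
#' @param counts_tsv,samples_tsv,gtf Paths to an externally produced segment
#'   count table, sample manifest and annotation (used when `sim` is NULL).
#' @param alpha,min_consistent,log2_cap Statistical parameters of the
#'   differential callers.
#' @param expression_threshold RPKM threshold for the expressed-gene
#'   filters.
#' @param candidate_genes Optional character vector of candidate gene ids
#'   for the candidate report.
#' @return List of class `RunConfig`.
#' @export
run_config <- function(out_dir, sim = sim_config(), counts_tsv = NULL,
                       samples_tsv = NULL, gtf = NULL, alpha = 0.05,
                       min_consistent = 4L, log2_cap = 20,
                       expression_threshold = 1.0, candidate_genes = NULL) {
  if (is.null(sim) && (is.null(counts_tsv) || is.null(samples_tsv) ||
                       is.null(gtf)))
    stopf("either `sim` or all of counts_tsv/samples_tsv/gtf must be given")
  structure(list(out_dir = out_dir, sim = sim, counts_tsv = counts_tsv,
                 samples_tsv = samples_tsv, gtf = gtf, alpha = alpha,
                 min_consistent = as.integer(min_consistent),
                 log2_cap = log2_cap,
                 expression_threshold = expression_threshold,
                 candidate_genes = candidate_genes),
            class = "RunConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

flatten_members <- function(segments) {
  segments$members <- vapply(segments$members, paste, "", collapse = ",")
  segments
}

#' Run the full analysis pipeline
#'
#' Executes segmentation, per-sample quantification, the gene- and
#' transcript-level differential callers, tissue enrichment against every
#' background sample, the similarity clustering and the expression reports,
#' writing every result as a TSV (plus a Newick dendrogram) and a JSON run
#' manifest under `config$out_dir`. Outputs carry no timestamps: rerunning
#' with an identical configuration reproduces the files byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results (`dataset`, `quant`,
#'   `de_genes`, `ds_transcripts`, `tissue`, `clustering`, `expressed`,
#'   `candidates`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name) message(sprintf("[isletseq] stage: %s", name))

  step("data")
  if (!is.null(config$sim)) {
    dataset <- simulate_dataset(config$sim)
  } else {
    ext <- read_counts_tsv(config$counts_tsv, config$samples_tsv)
    annotation <- parse_gtf(config$gtf)
    dataset <- structure(list(config = NULL, annotation = annotation,
                              segments = build_all_segments(annotation),
                              truth = NULL, samples = ext$samples,
                              counts = ext$counts[rownames(build_all_segments(annotation)), ,
                                                  drop = FALSE]),
                         class = "islet_sim")
  }
  files <- character()
  if (!is.null(config$sim)) files <- write_dataset(dataset, config$out_dir)
  chroms <- vapply(dataset$annotation, `[[`, "", "chromosome")
  files <- c(files, write_segments_bed(
    dataset$segments, file.path(config$out_dir, "segments.bed"), chroms))

  step("quantify")
  quant <- quantify_dataset(dataset)
  files <- c(files,
             write_tsv(quant$transcript,
                       file.path(config$out_dir, "transcript_quant.tsv")))
  gene_tab <- data.frame(gene_id = rownames(quant$gene_rpkm),
                         quant$gene_rpkm, check.names = FALSE)
  files <- c(files, write_tsv(gene_tab,
                              file.path(config$out_dir, "gene_rpkm.tsv")))

  step("differential genes")
  de <- differential_genes(quant, alpha = config$alpha,
                           min_consistent = config$min_consistent,
                           log2_cap = config$log2_cap)
  files <- c(files,
             write_tsv(de$per_pair, file.path(config$out_dir, "de_gene_pairs.tsv")),
             write_tsv(de$calls, file.path(config$out_dir, "de_gene_calls.tsv")))

  step("differential transcripts")
  ds <- differential_transcripts(quant, alpha = config$alpha,
                                 min_consistent = config$min_consistent)
  files <- c(files,
             write_tsv(ds$per_pair,
                       file.path(config$out_dir, "ds_transcript_pairs.tsv")),
             write_tsv(ds$calls,
                       file.path(config$out_dir, "ds_transcript_calls.tsv")))

  step("tissue enrichment")
  bg <- quant$samples$sample_id[quant$samples$condition == "background"]
  tissue <- lapply(bg, function(b)
    tissue_enrichment(quant, b, alpha = config$alpha,
                      min_consistent = config$min_consistent,
                      log2_cap = config$log2_cap))
  names(tissue) <- bg
  if (length(bg)) {
    tiss_tab <- do.call(rbind, lapply(bg, function(b) {
      x <- tissue[[b]]$calls
      x$background <- b
      x
    }))
    files <- c(files, write_tsv(tiss_tab,
                                file.path(config$out_dir,
                                          "tissue_enrichment.tsv")))
  }

  step("similarity")
  ctl_and_bg <- quant$samples$sample_id[quant$samples$condition %in%
                                          c("control", "background")]
  clustering <- sample_similarity(quant$gene_rpkm[, ctl_and_bg, drop = FALSE],
                                  threshold = config$expression_threshold)
  files <- c(files,
             write_tsv(pcc_table(clustering),
                       file.path(config$out_dir, "pairwise_pcc.tsv")),
             write_newick(clustering,
                          file.path(config$out_dir, "dendrogram.nwk")))

  step("report")
  ctl <- quant$samples$sample_id[quant$samples$condition == "control"]
  cyt <- quant$samples$sample_id[quant$samples$condition == "cytokine"]
  expressed <- expressed_gene_set(quant$gene_rpkm[, ctl, drop = FALSE],
                                  threshold = config$expression_threshold)
  de_sum <- de_summary(de$calls, expressed$n_expressed)
  candidates <- NULL
  if (!is.null(config$candidate_genes)) {
    candidates <- candidate_gene_report(
      config$candidate_genes,
      quant$gene_rpkm[, ctl, drop = FALSE],
      quant$gene_rpkm[, cyt, drop = FALSE],
      threshold = config$expression_threshold)
    files <- c(files, write_tsv(candidates$table,
                                file.path(config$out_dir,
                                          "candidate_report.tsv")))
  }

  manifest <- list(
    package = "isletseq",
    version = as.character(utils::packageVersion("isletseq")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    parameters = list(alpha = config$alpha,
                      min_consistent = config$min_consistent,
                      log2_cap = config$log2_cap,
                      expression_threshold = config$expression_threshold),
    sim = if (!is.null(config$sim)) unclass(config$sim) else NULL,
    n_genes = nrow(quant$gene_rpkm),
    n_transcripts = nrow(quant$tx_rpkm),
    n_segments = nrow(dataset$segments),
    n_samples = nrow(quant$samples),
    summary = list(
      n_expressed_median = expressed$n_expressed,
      n_expressed_in_all = expressed$n_in_all,
      median_genes_per_sample = expressed$median_genes_per_sample,
      n_genes_up = de_sum$n_up,
      n_genes_down = de_sum$n_down,
      pct_genes_modified = de_sum$pct_modified,
      n_transcripts_up = sum(ds$calls$call == "up"),
      n_transcripts_down = sum(ds$calls$call == "down"),
      pct_candidates_expressed = if (!is.null(candidates))
        candidates$pct_expressed else NA),
    outputs = sort(basename(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, quant = quant, de_genes = de,
                 ds_transcripts = ds, tissue = tissue,
                 clustering = clustering, expressed = expressed,
                 de_summary = de_sum, candidates = candidates,
                 manifest = manifest))
}
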