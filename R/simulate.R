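#' Configuration for the synthetic islet study generator
#'
#' Defaults emulate the paired five-donor islet design the pipeline was built
#' for: five control/cytokine sample pairs, about 35% of genes with more than
#' one annotated isoform, about 16% of genes with an injected cytokine effect,
#' library sizes spanning the 1e5--1e6 range (a documented scale-down of the
#' tens of millions of reads per lane in the emulated design), and a
#' splice-index shift of 0.3 in a subset of multi-isoform genes. Five
#' background tissue samples exercise the tissue-enrichment and clustering
#' stages.
#'
#' @param n_genes Number of genes to simulate.
#' @param frac_multi_isoform Proportion of genes with >= 2 transcripts.
#' @param n_sample_pairs Number of paired control/cytokine donors (>= 2).
#' @param library_size_range Two integers, min/max reads per sample.
#' @param frac_de_genes Proportion of genes with an injected expression
#'   effect in the cytokine condition.
#' @param de_log2fc_mag Magnitude of injected log2 fold changes; a single
#'   number for a fixed magnitude or a length-2 range sampled uniformly.
#' @param de_prob_up Probability an injected effect is an up-regulation.
#' @param frac_as_genes Proportion of multi-isoform genes with an injected
#'   splice-index shift (gene total preserved, so splicing effects are
#'   separable from expression effects).
#' @param as_shift Splice-index delta moved between the two major isoforms.
#' @param dispersion Overdispersion of counts; 0 gives multinomial sampling,
#'   values > 0 give Dirichlet-multinomial (gamma-perturbed proportions).
#' @param donor_sdlog Log-sd of the per-donor lognormal scaling factor shared
#'   between a donor's control and cytokine samples (paired design).
#' @param expr_sdlog Log-sd of baseline gene expression across genes
#'   (heavy-tailed, Zipf-like expression distribution).
#' @param background_tissues Names of independent background tissue samples.
#' @param seed Integer seed; identical configs give byte-identical datasets.
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 200L,
                       frac_multi_isoform = 0.35,
                       n_sample_pairs = 5L,
                       library_size_range = c(1e5, 1e6),
                       frac_de_genes = 0.16,
                       de_log2fc_mag = 2,
                       de_prob_up = 0.5,
                       frac_as_genes = 0.3,
                       as_shift = 0.3,
                       dispersion = 0,
                       donor_sdlog = 0.25,
                       expr_sdlog = 1.5,
                       background_tissues = c("adipose", "colon", "kidney",
                                              "liver", "muscle"),
                       seed = 1L) {
  for (p in c(frac_multi_isoform, frac_de_genes, frac_as_genes, de_prob_up))
    if (p < 0 || p > 1) stopf("proportions must lie in [0,1]")
  if (n_sample_pairs < 2L) stopf("n_sample_pairs must be >= 2")
  if (any(library_size_range <= 0) || length(library_size_range) != 2L)
    stopf("library_size_range must be two positive numbers")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes),
    frac_multi_isoform = frac_multi_isoform,
    n_sample_pairs = as.integer(n_sample_pairs),
    library_size_range = sort(as.numeric(library_size_range)),
    frac_de_genes = frac_de_genes,
    de_log2fc_mag = de_log2fc_mag,
    de_prob_up = de_prob_up,
    frac_as_genes = frac_as_genes,
    as_shift = as_shift,
    dispersion = dispersion,
    donor_sdlog = donor_sdlog,
    expr_sdlog = expr_sdlog,
    background_tissues = background_tissues,
    seed = as.integer(seed)), class = "SimConfig")
}

#' Simulate a transcript annotation
#'
#' Generates `n_genes` gene models on a synthetic chromosome. The requested
#' fraction of genes carries 2--3 isoforms constructed so that at least one
#' exonic segment distinguishes the isoforms (a skipped internal exon, and
#' for three-isoform genes additionally a shortened 3' end); the remaining
#' genes are single-isoform. Deterministic given `config$seed` when called
#' directly; inside [simulate_dataset()] it uses the surrounding RNG stream.
#'
#' @param config A [sim_config()].
#' @param .reseed Set the RNG from `config$seed` (default TRUE when used
#'   standalone).
#' @return A `GeneAnnotation` list of `GeneModel`s.
#' @export
simulate_annotation <- function(config, .reseed = TRUE) {
  if (.reseed) set.seed(config$seed)
  n <- config$n_genes
  n_multi <- round(config$frac_multi_isoform * n)
  is_multi <- rep(FALSE, n)
  if (n_multi > 0) is_multi[sample.int(n, n_multi)] <- TRUE
  pos <- 0
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    gid <- sprintf("G%04d", i)
    n_exons <- sample(4:8, 1L)
    widths <- sample(80:300, n_exons, replace = TRUE)
    gaps <- sample(50:200, n_exons, replace = TRUE)
    starts <- pos + cumsum(gaps) + c(0, cumsum(widths))[seq_len(n_exons)]
    exons <- cbind(start = starts, end = starts + widths)
    pos <- max(exons[, 2L]) + 1000
    strand <- sample(c("+", "-"), 1L)
    txs <- list(new_transcript(paste0(gid, ".t1"), gid, exons))
    if (is_multi[i]) {
      skip <- sample(2:(n_exons - 1L), 1L)
      txs <- c(txs, list(new_transcript(paste0(gid, ".t2"), gid,
                                        exons[-skip, , drop = FALSE])))
      if (stats::runif(1) < 0.4 && n_exons >= 5L) {
        # third isoform with a shortened 3' end
        txs <- c(txs, list(new_transcript(paste0(gid, ".t3"), gid,
                                          exons[seq_len(n_exons - 1L), ,
                                                drop = FALSE])))
      }
    }
    genes[[i]] <- new_gene_model(gid, "chrS", strand, txs)
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(genes, class = "GeneAnnotation")
}

#' Draw baseline ground-truth abundances
#'
#' Baseline gene expression is lognormal across genes (heavy-tailed), and
#' isoform usage within multi-isoform genes is drawn from a symmetric
#' Dirichlet. Transcript abundance is expressed in relative reads-per-base
#' units, so the true splice index of a transcript equals its abundance
#' weight within the gene.
#'
#' @param annotation A `GeneAnnotation`.
#' @param config A [sim_config()].
#' @param .reseed See [simulate_annotation()].
#' @return data.frame of class `GroundTruth`: one row per transcript with
#'   control/cytokine abundances, true DE direction/log2FC and AS flags.
#' @export
simulate_truth <- function(annotation, config, .reseed = TRUE) {
  if (.reseed) set.seed(config$seed + 1L)
  rows <- lapply(annotation, function(g) {
    k <- length(g$transcripts)
    x <- stats::rlnorm(1, meanlog = 1, sdlog = config$expr_sdlog)
    w <- stats::rgamma(k, shape = 2)
    w <- w / sum(w)
    data.frame(gene_id = g$gene_id,
               transcript_id = names(g$transcripts),
               length_bp = vapply(g$transcripts, `[[`, 0, "length_bp"),
               gene_expr = x,
               si_ctl = w,
               si_cyt = w,
               log2fc = 0,
               de = "none",
               as_gene = FALSE,
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  rownames(truth) <- truth$transcript_id
  truth$abundance_ctl <- truth$gene_expr * truth$si_ctl
  truth$abundance_cyt <- truth$gene_expr * truth$si_cyt
  class(truth) <- c("GroundTruth", "data.frame")
  truth
}

#' Inject cytokine expression and splicing effects into a ground truth
#'
#' Marks `frac_de_genes` of all genes as differentially expressed with a
#' signed log2 fold change applied to the cytokine abundances, and shifts the
#' splice index of `frac_as_genes` of the multi-isoform genes by `as_shift`
#' (moved from the minor to the major isoform) while preserving the gene
#' total, so splicing and expression effects are separable. Genes where the
#' shift would push an index outside [0,1] are skipped with a warning.
#'
#' @param truth A `GroundTruth` from [simulate_truth()].
#' @param config A [sim_config()].
#' @param .reseed See [simulate_annotation()].
#' @return The modified `GroundTruth`.
#' @export
inject_effects <- function(truth, config, .reseed = TRUE) {
  if (.reseed) set.seed(config$seed + 2L)
  genes <- unique(truth$gene_id)
  n_de <- round(config$frac_de_genes * length(genes))
  de_genes <- if (n_de > 0) sample(genes, n_de) else character()
  # expected read mass of a gene (abundance x transcript length); kept
  # balanced across injected effects so that unaffected genes stay null
  # after library-size normalization (counts are compositional)
  gene_mass <- vapply(de_genes, function(g) {
    idx <- truth$gene_id == g
    sum(truth$gene_expr[idx] * truth$si_ctl[idx] * truth$length_bp[idx])
  }, 0)
  mags <- vapply(de_genes, function(g) {
    if (length(config$de_log2fc_mag) == 2L)
      stats::runif(1, config$de_log2fc_mag[1L], config$de_log2fc_mag[2L])
    else config$de_log2fc_mag
  }, 0)
  if (length(de_genes)) {
    if (config$de_prob_up == 0.5) {
      # balanced design: assign signs greedily (largest mass first) so the
      # net injected mass change is near zero
      o <- order(gene_mass * (2^mags - 1), decreasing = TRUE)
      running <- 0
      sgn <- numeric(length(de_genes))
      for (i in o) {
        d_up <- gene_mass[i] * (2^mags[i] - 1)
        d_dn <- gene_mass[i] * (2^-mags[i] - 1)
        sgn[i] <- if (abs(running + d_up) <= abs(running + d_dn)) 1 else -1
        running <- running + if (sgn[i] > 0) d_up else d_dn
      }
    } else {
      sgn <- ifelse(stats::runif(length(de_genes)) < config$de_prob_up, 1, -1)
    }
    for (k in seq_along(de_genes)) {
      idx <- truth$gene_id == de_genes[k]
      truth$log2fc[idx] <- sgn[k] * mags[k]
      truth$de[idx] <- if (sgn[k] > 0) "up" else "down"
    }
  }
  multi <- names(which(table(truth$gene_id) >= 2L))
  n_as <- round(config$frac_as_genes * length(multi))
  as_genes <- if (n_as > 0) sample(multi, n_as) else character()
  for (g in as_genes) {
    idx <- which(truth$gene_id == g)
    w <- truth$si_cyt[idx]
    o <- order(w, decreasing = TRUE)
    gain <- idx[o[1L]]; lose <- idx[o[2L]]
    if (truth$si_cyt[gain] + config$as_shift > 1 ||
        truth$si_cyt[lose] - config$as_shift < 0) {
      warnf("gene '%s': splice-index shift %.2f infeasible, skipped",
            g, config$as_shift)
      next
    }
    w_new <- truth$si_cyt[idx]
    w_new[which(idx == gain)] <- w_new[which(idx == gain)] + config$as_shift
    w_new[which(idx == lose)] <- w_new[which(idx == lose)] - config$as_shift
    # rescale so the gene's expected read mass is unchanged by the shift:
    # splicing effects must not masquerade as expression effects
    len <- truth$length_bp[idx]
    scale <- sum(truth$si_cyt[idx] * len) / sum(w_new * len)
    truth$si_cyt[idx] <- w_new
    truth$gene_expr_cyt_scale <- truth$gene_expr_cyt_scale %||% rep(1, nrow(truth))
    truth$gene_expr_cyt_scale[idx] <- truth$gene_expr_cyt_scale[idx] * scale
    truth$as_gene[idx] <- TRUE
  }
  if (is.null(truth$gene_expr_cyt_scale))
    truth$gene_expr_cyt_scale <- rep(1, nrow(truth))
  truth$abundance_ctl <- truth$gene_expr * truth$si_ctl
  truth$abundance_cyt <- truth$gene_expr * truth$gene_expr_cyt_scale *
    2^truth$log2fc * truth$si_cyt
  # exact compositional null: counts are proportions of the library, so a
  # net mass change among DE genes would shift every null gene's expected
  # proportion. Scale the null genes' cytokine abundances by the DE genes'
  # mass ratio, which equalizes null proportions between conditions exactly
  # (the proportion-scale fold change realized for a DE gene is then
  # 2^log2fc divided by this factor; the greedy sign balance keeps the
  # factor near 1, and it is recorded as an attribute).
  is_de <- truth$de != "none"
  if (any(is_de)) {
    mass_ctl <- sum(truth$abundance_ctl[is_de] * truth$length_bp[is_de])
    mass_cyt <- sum(truth$abundance_cyt[is_de] * truth$length_bp[is_de])
    cfac <- mass_cyt / mass_ctl
    truth$abundance_cyt[!is_de] <- truth$abundance_cyt[!is_de] * cfac
    attr(truth, "null_composition_factor") <- cfac
  } else {
    attr(truth, "null_composition_factor") <- 1
  }
  truth
}

#' Expected segment read counts for given transcript abundances
#'
#' The observation model: the expected number of reads in a segment is the
#' sum over member transcripts of abundance (reads per base) times segment
#' length.
#'
#' @param segments Segment table from [build_all_segments()].
#' @param abundance Named numeric vector of transcript abundances.
#' @return Numeric vector of expected counts, one per segment row.
#' @export
expected_segment_counts <- function(segments, abundance) {
  vapply(seq_len(nrow(segments)), function(i) {
    m <- segments$members[[i]]
    sum(abundance[m]) * segments$length[i]
  }, 0)
}

# sample one library: multinomial or Dirichlet-multinomial around p
draw_counts <- function(p, size, dispersion, expected_mode) {
  if (expected_mode) return(round(size * p))
  if (dispersion > 0) {
    g <- stats::rgamma(length(p), shape = p / dispersion)
    if (sum(g) == 0) g <- p
    p <- g / sum(g)
  }
  as.numeric(stats::rmultinom(1L, size = round(size), prob = p))
}

#' Simulate per-sample segment counts
#'
#' For each donor pair, a shared lognormal donor factor scales both samples'
#' abundances (it cancels within the pair, matching the paired design). Each
#' background tissue is an independent abundance draw over the same
#' annotation, giving low correlation with the islet profile. Expected
#' segment counts follow [expected_segment_counts()], scaled so the sample
#' total matches its drawn library size; realized counts are multinomial
#' (or Dirichlet-multinomial for `dispersion > 0`).
#'
#' @param annotation A `GeneAnnotation`.
#' @param segments Segment table from [build_all_segments()].
#' @param truth `GroundTruth` (after [inject_effects()]).
#' @param config A [sim_config()].
#' @param expected_mode If TRUE, counts equal rounded expectations exactly
#'   (noiseless mode for recovery tests).
#' @param .reseed See [simulate_annotation()].
#' @return List with `samples` (data.frame: sample_id, condition, donor_id,
#'   tissue, library_size, total_mapped_reads) and `counts` (segments x
#'   samples numeric matrix).
#' @export
simulate_counts <- function(annotation, segments, truth, config,
                            expected_mode = FALSE, .reseed = TRUE) {
  if (.reseed) set.seed(config$seed + 3L)
  if (all(truth$abundance_ctl == 0) || all(truth$abundance_cyt == 0))
    stopf("all-zero abundance vector")
  n_pairs <- config$n_sample_pairs
  tissues <- config$background_tissues
  sample_ids <- c(rbind(sprintf("ctl_D%d", seq_len(n_pairs)),
                        sprintf("cyt_D%d", seq_len(n_pairs))),
                  if (length(tissues)) paste0("bg_", tissues))
  conditions <- c(rep(c("control", "cytokine"), n_pairs),
                  rep("background", length(tissues)))
  donors <- c(rep(sprintf("D%d", seq_len(n_pairs)), each = 2L),
              rep(NA_character_, length(tissues)))
  tissue_col <- c(rep("islet", 2L * n_pairs), tissues)

  lib_sizes <- round(stats::runif(length(sample_ids),
                                  config$library_size_range[1L],
                                  config$library_size_range[2L]))
  donor_factor <- stats::rlnorm(n_pairs, 0, config$donor_sdlog)

  counts <- matrix(0, nrow = nrow(segments), ncol = length(sample_ids),
                   dimnames = list(segments$segment_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    cond <- conditions[j]
    if (cond == "background") {
      x <- stats::rlnorm(length(annotation), meanlog = 1,
                         sdlog = config$expr_sdlog)
      names(x) <- names(annotation)
      k <- vapply(annotation, function(g) length(g$transcripts), 0L)
      w <- stats::rgamma(sum(k), shape = 2)
      ab <- numeric(nrow(truth)); names(ab) <- truth$transcript_id
      off <- 0L
      for (gi in seq_along(annotation)) {
        idx <- off + seq_len(k[gi]); off <- off + k[gi]
        wi <- w[idx] / sum(w[idx])
        ab[names(annotation[[gi]]$transcripts)] <- x[gi] * wi
      }
    } else {
      ab <- if (cond == "control") truth$abundance_ctl else truth$abundance_cyt
      names(ab) <- truth$transcript_id
      ab <- ab * donor_factor[match(donors[j], sprintf("D%d", seq_len(n_pairs)))]
    }
    e <- expected_segment_counts(segments, ab)
    counts[, j] <- draw_counts(e / sum(e), lib_sizes[j],
                               config$dispersion, expected_mode)
  }
  samples <- data.frame(
    sample_id = sample_ids, condition = conditions, donor_id = donors,
    tissue = tissue_col, library_size = lib_sizes,
    total_mapped_reads = colSums(counts),
    stringsAsFactors = FALSE)
  list(samples = samples, counts = counts)
}

#' Simulate a complete study dataset
#'
#' Runs annotation simulation, ground-truth drawing, effect injection,
#' segmentation and count simulation with a single seed, yielding a fully
#' reproducible dataset.
#'
#' @param config A [sim_config()].
#' @param expected_mode Passed to [simulate_counts()].
#' @return List of class `islet_sim` with elements `config`, `annotation`,
#'   `segments`, `truth`, `samples`, `counts`.
#' @export
simulate_dataset <- function(config = sim_config(), expected_mode = FALSE) {
  annotation <- simulate_annotation(config)
  truth <- simulate_truth(annotation, config)
  truth <- inject_effects(truth, config)
  segments <- build_all_segments(annotation)
  obs <- simulate_counts(annotation, segments, truth, config,
                         expected_mode = expected_mode)
  structure(list(config = config, annotation = annotation,
                 segments = segments, truth = truth,
                 samples = obs$samples, counts = obs$counts),
            class = "islet_sim")
}

#' Write a simulated dataset to disk
#'
#' Writes the annotation (GTF), the per-segment count table (TSV with
#' columns gene_id, segment_id, start, end, members and one column per
#' sample), the sample manifest (TSV) and the ground truth (JSON).
#'
#' @param dataset An `islet_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_gtf <- file.path(dir, "annotation.gtf")
  write_gtf(dataset$annotation, f_gtf)
  seg <- dataset$segments
  tab <- data.frame(gene_id = seg$gene_id, segment_id = seg$segment_id,
                    start = seg$start, end = seg$end,
                    members = vapply(seg$members, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(dataset$counts))
  f_counts <- file.path(dir, "segment_counts.tsv")
  utils::write.table(tab, f_counts, sep = "\t", quote = FALSE, row.names = FALSE)
  f_samples <- file.path(dir, "samples.tsv")
  utils::write.table(dataset$samples, f_samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, f_truth, digits = NA, pretty = TRUE)
  invisible(c(f_gtf, f_counts, f_samples, f_truth))
}

#' Read a segment count table written by [write_dataset()]
#'
#' @param counts_path Path to `segment_counts.tsv`.
#' @param samples_path Path to `samples.tsv`.
#' @return List with `segments`, `counts` matrix and `samples` data.frame.
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  samples <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  meta_cols <- c("gene_id", "segment_id", "start", "end", "members")
  counts <- as.matrix(tab[, setdiff(colnames(tab), meta_cols), drop = FALSE])
  rownames(counts) <- tab$segment_id
  segments <- tab[, meta_cols]
  segments$members <- strsplit(segments$members, ",", fixed = TRUE)
  segments$length <- segments$end - segments$start
  rownames(segments) <- segments$segment_id
  list(segments = segments, counts = counts, samples = samples)
}
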