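# isletseq

Transcript-level analysis of paired control/cytokine RNA-seq from human
pancreatic islets, built for the study design in which islet preparations
from five organ donors are cultured with or without the pro-inflammatory
cytokines IL-1β + IFN-γ and compared against a panel of background
tissues. The package is aimed at analysts who have (or simulate)
segment-level read counts and want the complete downstream pipeline —
isoform deconvolution, RPKM/splice-index quantification, cytokine-response
calling, tissue enrichment and sample clustering — as tested, reusable R
functions.

## What it computes

* **Exonic segments.** Each gene's transcripts are projected onto the
  maximal intervals with constant transcript membership; segments are the
  observation unit for counting and deconvolution.
* **Deconvolution.** Per gene, transcript abundances θ solve
  `min ‖Aθ − c‖², θ ≥ 0`, with `A[s,t] = length(s)` for member transcripts
  and `c` the segment counts; assigned reads are `θ_t · length(t)`.
  Expression is reported in RPKM, and each transcript's **splice index**
  is its share of the gene's RPKM sum.
* **Cytokine-response calling.** Per gene and donor pair, a two-sided
  Fisher exact test on gene reads vs all-other-gene reads (cytokine vs
  control); Benjamini–Hochberg correction across the five pairs of each
  gene; a gene is called up (down) only if significant in that direction
  in ≥ 4 of 5 pairs with no pair significant in the opposite direction.
  The same machinery applied within genes to deconvolved transcript reads
  calls cytokine-modified spliceforms, and applied against single
  background-tissue samples calls islet-enriched/-depleted genes.
* **Similarity.** Genes with RPKM > 1 in all samples, log10 (power-law)
  normalization, Pearson correlation, complete-linkage clustering on
  (1 − PCC), Newick export.
* **Synthetic data.** `sim_config()` / `simulate_dataset()` generate
  ground-truth-annotated datasets emulating the five-donor design
  (paired samples, ~35% multi-isoform genes, ~16% injected effects,
  splice-index shifts, background tissues), so the whole pipeline is
  testable end to end without external data.

## Worked example

```r
library(isletseq)

cfg <- sim_config(n_genes = 100, seed = 42)  # 5 donor pairs + 5 tissues
ds  <- simulate_dataset(cfg)
quant <- quantify_dataset(ds)

de  <- differential_genes(quant)
ctl <- quant$samples$sample_id[quant$samples$condition == "control"]
expressed <- expressed_gene_set(quant$gene_rpkm[, ctl])
s <- de_summary(de$calls, expressed$n_expressed)

cat("genes expressed (median RPKM > 1):", expressed$n_expressed, "\n")
cat("cytokine-modified:", s$n_modified, sprintf("(%d%%),", s$pct_modified),
    s$n_up, "up /", s$n_down, "down\n")
head(de$calls[de$calls$call != "unchanged", ], 3)
```

```
genes expressed (median RPKM > 1): 100
cytokine-modified: 16 (16%), 1 up / 15 down
  unit_id call n_significant_up n_significant_down median_significant_effect
1   G0001 down                0                  5                 -2.214928
5   G0005 down                0                  5                 -2.218077
6   G0006 down                0                  5                 -2.338839
```

All 16 genes carrying injected effects are recovered (the generator
injected 16% of 100 genes) and no unaffected gene is called; the median
significant effect is the log2 RPKM ratio across the significant pairs.
`run_pipeline(run_config(out_dir, sim = cfg))` runs every stage —
quantification, gene/transcript calling, tissue enrichment, clustering,
reports — and writes TSV/Newick/JSON outputs plus a run manifest;
rerunning the same configuration reproduces the outputs byte for byte.

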