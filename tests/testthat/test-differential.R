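test_that("gene-pair Fisher test matches hand-enumerated values", {
  # no association
  r <- fisher_gene_pair(5, 10, 5, 10)
  expect_equal(r$p, 1.0)
  expect_equal(r$direction_sign, 0)
  # perfectly divergent table [[0,10],[10,0]]: p = 2 / C(20,10)
  r2 <- fisher_gene_pair(0, 10, 10, 10)
  expect_equal(r2$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r2$direction_sign, -1)
  # moderate association, value fixed by the enumeration oracle
  r3 <- fisher_gene_pair(30, 1000, 10, 1000)
  expect_equal(r3$p, fisher_enum_oracle(30, 970, 10, 990), tolerance = 1e-12)
  expect_equal(r3$direction_sign, 1)
  expect_error(fisher_gene_pair(20, 10, 5, 10), "exceed")
})

test_that("transcript-pair Fisher test agrees with the oracle and flags direction", {
  r <- fisher_transcript_pair(50, 50, 50, 50)
  expect_equal(r$p, 1.0)
  r2 <- fisher_transcript_pair(40, 10, 10, 40)
  expect_equal(r2$p, fisher_enum_oracle(40, 10, 10, 40), tolerance = 1e-12)
  expect_equal(r2$direction_sign, 1)
})

test_that("Fisher p equals the enumeration oracle and fisher.test on random tables", {
  set.seed(19)
  for (i in 1:300) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    c <- sample(0:40, 1); d <- sample(0:40, 1)
    if ((a + b) == 0 || (c + d) == 0) next
    p <- fisher_transcript_pair(a, b, c, d)$p
    expect_equal(p, fisher_enum_oracle(a, b, c, d), tolerance = 1e-12,
                 label = sprintf("table %d %d %d %d", a, b, c, d))
  }
  # spot cross-check against stats::fisher.test
  for (tab in list(c(3, 17, 9, 4), c(0, 25, 12, 13), c(7, 7, 7, 7))) {
    expect_equal(
      fisher_transcript_pair(tab[1], tab[2], tab[3], tab[4])$p,
      stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
      tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(29)
  for (i in 1:200) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("log2 expression change uses the documented cap sentinel", {
  expect_equal(log2_expression_change(8, 2), 2)
  expect_equal(log2_expression_change(3, 3), 0)
  expect_equal(log2_expression_change(5, 0), 20)
  expect_equal(log2_expression_change(0, 5), -20)
  expect_equal(log2_expression_change(5, 0, cap = 10), 10)
  expect_true(is.na(log2_expression_change(0, 0)))
})

test_that("splice-index differences propagate undefined values", {
  expect_equal(delta_splice_index(0.8, 0.5), 0.3)
  expect_equal(delta_splice_index(0.5, 0.5), 0)
  expect_true(is.na(delta_splice_index(NA, 0.5)))
})

test_that("directional consistency rule: 4-of-5 same direction, none opposite", {
  p <- c(0.01, 0.01, 0.01, 0.01, 0.5)
  expect_equal(call_unit(p, c(1, 1, 1, 1, 1))$call, "up")
  expect_equal(call_unit(p, c(1, 1, 1, 1, -1))$call, "up") # 5th not significant
  expect_equal(call_unit(rep(0.01, 5), c(1, 1, 1, 1, -1))$call, "unchanged")
  expect_equal(call_unit(c(0.01, 0.01, 0.01, 0.5, 0.5), rep(1, 5))$call,
               "unchanged")
  expect_equal(call_unit(p, c(-1, -1, -1, -1, 0))$call, "down")
  # ties (direction 0) never count toward either side
  expect_equal(call_unit(rep(0.001, 5), c(0, 0, 0, 0, 0))$call, "unchanged")
  expect_error(call_unit(c(0.1, 0.2), c(1, 1)), "min_consistent")
})

test_that("swapping conditions flips directions and preserves p-values", {
  set.seed(37)
  for (i in 1:50) {
    g1 <- sample(0:500, 1); t1 <- g1 + sample(500:5000, 1)
    g2 <- sample(0:500, 1); t2 <- g2 + sample(500:5000, 1)
    f <- fisher_gene_pair(g1, t1, g2, t2)
    fr <- fisher_gene_pair(g2, t2, g1, t1)
    expect_equal(f$p, fr$p, tolerance = 1e-12)
    expect_equal(f$direction_sign, -fr$direction_sign)
  }
  expect_equal(log2_expression_change(8, 2), -log2_expression_change(2, 8))
})

test_that("gene caller recovers injected effects and stays quiet on nulls", {
  cfg <- sim_config(n_genes = 50, frac_de_genes = 0.2, de_log2fc_mag = 2,
                    frac_as_genes = 0, seed = 41)
  ds <- suppressWarnings(simulate_dataset(cfg))
  q <- quantify_dataset(ds)
  de <- differential_genes(q)
  truth <- unique(ds$truth[, c("gene_id", "de")])
  m <- merge(de$calls, truth, by.x = "unit_id", by.y = "gene_id")
  expect_true(all(m$call[m$de == "none"] == "unchanged"))
  called <- m[m$de != "none", ]
  expect_gte(mean(called$call == called$de), 0.9)
  # per-pair table invariants
  expect_true(all(de$per_pair$p_adj >= de$per_pair$p_raw - 1e-12))
  expect_true(all(de$per_pair$p_adj <= 1))
})

test_that("transcript caller: expression-only changes do not mimic real splicing shifts", {
  # A pure expression change leaves within-gene read proportions unchanged
  # in expectation, but the plug-in splice index carries a depth-dependent
  # ratio bias, so a minority of strongly-shifted genes can reach nominal
  # significance. Such spurious calls must stay a minority and their
  # splice-index effects must be an order of magnitude below a genuine
  # shift (0.3), so they remain distinguishable by effect size.
  cfg <- sim_config(n_genes = 40, frac_multi_isoform = 1, frac_de_genes = 0.5,
                    de_log2fc_mag = 2, frac_as_genes = 0, seed = 43)
  ds <- simulate_dataset(cfg)
  q <- quantify_dataset(ds)
  dstx <- differential_transcripts(q)
  called <- dstx$calls[dstx$calls$call != "unchanged", ]
  expect_lte(nrow(called) / nrow(dstx$calls), 0.15)
  if (nrow(called))
    expect_true(all(abs(called$median_significant_effect) < 0.1))
  # with no expression change at all, the transcript caller is silent
  cfg0 <- sim_config(n_genes = 40, frac_multi_isoform = 1, frac_de_genes = 0,
                     frac_as_genes = 0, seed = 43)
  ds0 <- simulate_dataset(cfg0)
  dstx0 <- differential_transcripts(quantify_dataset(ds0))
  expect_lte(mean(dstx0$calls$call != "unchanged"), 0.05)
})

test_that("transcript caller skips single-isoform genes", {
  cfg <- sim_config(n_genes = 20, frac_multi_isoform = 0.5, frac_de_genes = 0,
                    frac_as_genes = 0, seed = 47)
  ds <- simulate_dataset(cfg)
  q <- quantify_dataset(ds)
  dstx <- differential_transcripts(q)
  n_single <- sum(table(q$gene_of_tx) == 1L)
  expect_length(dstx$skipped, n_single)
  expect_false(any(dstx$skipped %in% dstx$calls$unit_id))
})

test_that("tissue enrichment flags strongly islet-enriched genes only", {
  cfg <- sim_config(n_genes = 30, frac_de_genes = 0, frac_as_genes = 0,
                    seed = 53)
  ds <- simulate_dataset(cfg)
  q <- quantify_dataset(ds)
  bg <- q$samples$sample_id[q$samples$condition == "background"][1L]
  te <- tissue_enrichment(q, bg)
  # directions of calls must match the median significant log2 difference
  up <- te$calls[te$calls$call == "up", ]
  if (nrow(up)) expect_true(all(up$median_significant_effect > 0))
  dn <- te$calls[te$calls$call == "down", ]
  if (nrow(dn)) expect_true(all(dn$median_significant_effect < 0))
  # identical profile (islet sample vs itself as background) gives no calls
  te_self <- tissue_enrichment(q, q$samples$sample_id[1L],
                               islet_samples = rep(q$samples$sample_id[1L], 5))
  expect_true(all(te_self$calls$call == "unchanged"))
})
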