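test_that("annotation simulation honors the multi-isoform fraction and is reproducible", {
  cfg0 <- sim_config(n_genes = 10, frac_multi_isoform = 0, seed = 3)
  ann0 <- simulate_annotation(cfg0)
  expect_true(all(vapply(ann0, function(g) length(g$transcripts), 0L) == 1L))

  cfg1 <- sim_config(n_genes = 10, frac_multi_isoform = 1, seed = 3)
  ann1 <- simulate_annotation(cfg1)
  expect_true(all(vapply(ann1, function(g) length(g$transcripts), 0L) >= 2L))
  # every gene has a transcript-distinguishing segment (proper member subset)
  for (g in ann1) {
    seg <- build_segments(g)
    proper <- vapply(seg$members, function(m)
      length(m) < length(g$transcripts), NA)
    expect_true(any(proper), label = g$gene_id)
  }

  expect_identical(simulate_annotation(cfg1), simulate_annotation(cfg1))
})

test_that("identical config gives byte-identical datasets on disk", {
  cfg <- sim_config(n_genes = 15, seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(suppressWarnings(simulate_dataset(cfg)), d1)
  write_dataset(suppressWarnings(simulate_dataset(cfg)), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("expected segment counts follow the linear observation model", {
  g <- fixture_gene()  # T1 len 200, T2 len 150
  seg <- build_segments(g)
  e <- expected_segment_counts(seg, c(T1 = 2, T2 = 4))
  expect_equal(e, c(600, 100, 300))
  # doubling abundances with a fixed library size leaves proportions unchanged
  e2 <- expected_segment_counts(seg, c(T1 = 4, T2 = 8))
  expect_equal(e2 / sum(e2), e / sum(e))
})

test_that("counts conserve totals and expected mode reproduces scaled expectations", {
  cfg <- sim_config(n_genes = 20, seed = 5)
  ds <- suppressWarnings(simulate_dataset(cfg))
  expect_equal(colSums(ds$counts), ds$samples$total_mapped_reads,
               ignore_attr = TRUE)
  expect_true(all(ds$counts >= 0))

  dse <- suppressWarnings(simulate_dataset(cfg, expected_mode = TRUE))
  ab <- setNames(ds$truth$abundance_ctl, ds$truth$transcript_id)
  e <- expected_segment_counts(dse$segments, ab)
  s1 <- dse$samples$sample_id[dse$samples$condition == "control"][1L]
  donor_scaled <- e / sum(e) * dse$samples$library_size[dse$samples$sample_id == s1]
  expect_equal(unname(dse$counts[, s1]), round(donor_scaled))
})

test_that("effect injection: DE scales gene totals, AS shifts splice indices, both separable", {
  cfg <- sim_config(n_genes = 40, frac_multi_isoform = 1, frac_de_genes = 0.25,
                    de_log2fc_mag = 2, frac_as_genes = 0.5, seed = 21)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  truth <- suppressWarnings(inject_effects(truth, cfg))

  up <- truth[truth$de == "up" & !truth$as_gene, ]
  if (nrow(up)) {
    tot_cyt <- tapply(up$abundance_cyt, up$gene_id, sum)
    tot_ctl <- tapply(up$abundance_ctl, up$gene_id, sum)
    expect_equal(as.vector(tot_cyt / tot_ctl), rep(4, length(tot_cyt)))
  }
  # splice indices remain valid proportions
  si_sums <- tapply(truth$si_cyt, truth$gene_id, sum)
  expect_equal(as.vector(si_sums), rep(1, length(si_sums)), tolerance = 1e-12)
  expect_true(all(truth$si_cyt >= 0 & truth$si_cyt <= 1))
  # the compositional correction keeps all null genes at a single common
  # scale, so their expected proportions match control exactly
  null_gene <- truth$de == "none" & !truth$as_gene
  ratio <- truth$abundance_cyt[null_gene] / truth$abundance_ctl[null_gene]
  expect_lt(diff(range(ratio)), 1e-12)

  # AS genes in a DE-free config: splice-index shift of +/- as_shift on the
  # two major isoforms with the expected read mass preserved exactly
  cfg_as <- sim_config(n_genes = 30, frac_multi_isoform = 1,
                       frac_de_genes = 0, frac_as_genes = 0.5, seed = 22)
  ann_as <- simulate_annotation(cfg_as)
  tr_as <- suppressWarnings(inject_effects(simulate_truth(ann_as, cfg_as),
                                           cfg_as))
  for (g in unique(tr_as$gene_id[tr_as$as_gene])) {
    idx <- tr_as$gene_id == g
    dsi <- tr_as$si_cyt[idx] - tr_as$si_ctl[idx]
    expect_equal(sort(abs(dsi[dsi != 0])), rep(cfg_as$as_shift, 2))
    mass_ctl <- sum(tr_as$abundance_ctl[idx] * tr_as$length_bp[idx])
    mass_cyt <- sum(tr_as$abundance_cyt[idx] * tr_as$length_bp[idx])
    expect_equal(mass_cyt, mass_ctl, tolerance = 1e-12)
  }
})

test_that("no injected effects means equal expected totals for every gene", {
  cfg <- sim_config(n_genes = 25, frac_de_genes = 0, frac_as_genes = 0,
                    seed = 13)
  ann <- simulate_annotation(cfg)
  truth <- inject_effects(simulate_truth(ann, cfg), cfg)
  expect_equal(truth$abundance_cyt, truth$abundance_ctl)
})

test_that("infeasible splice-index shift is skipped with a warning", {
  cfg <- sim_config(n_genes = 1, frac_multi_isoform = 1, frac_de_genes = 0,
                    frac_as_genes = 1, as_shift = 0.95, seed = 2)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  expect_warning(t2 <- inject_effects(truth, cfg), "infeasible")
})

test_that("empirical segment proportions converge to expectations at high depth", {
  cfg <- sim_config(n_genes = 10, frac_de_genes = 0, frac_as_genes = 0,
                    library_size_range = c(2e6, 2e6), seed = 31)
  ds <- simulate_dataset(cfg)
  ab <- setNames(ds$truth$abundance_ctl, ds$truth$transcript_id)
  e <- expected_segment_counts(ds$segments, ab)
  s1 <- ds$samples$sample_id[1L]
  donor <- sum(ds$counts[, s1])
  expected <- e / sum(e) * donor
  big <- expected >= 1000
  expect_true(any(big))
  rel <- abs(ds$counts[big, s1] - expected[big]) / expected[big]
  expect_true(all(rel < 0.1))
  expect_lt(mean(rel), 0.02)
})
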