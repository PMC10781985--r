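test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 4)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$models$genes, g2$models$genes)
  expect_identical(g1$truth, g2$truth)
  m1 <- simulate_methylation(g1, cfg)
  m2 <- simulate_methylation(g2, cfg)
  expect_identical(m1$compartments, m2$compartments)
  mk1 <- simulate_mark_tracks(g1, cfg)
  c1 <- simulate_cells(g1, mk1, cfg)
  c2 <- simulate_cells(g2, simulate_mark_tracks(g2, cfg), cfg)
  expect_identical(c1$peaks_mat, c2$peaks_mat)
  expect_identical(c1$genes_mat, c2$genes_mat)
  # a different seed changes the draw
  g3 <- simulate_genome(sim_config(seed = 5))
  expect_false(identical(g1$models$genes, g3$models$genes))
})

test_that("planted feature counts match the emitted artifacts", {
  cfg <- sim_config(seed = 6)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$models$genes), cfg$n_genes)
  rs <- g$truth$region_states
  expect_equal(sum(rs$state == "predicted_enhancer"),
               cfg$n_chroms * cfg$enhancers_per_chrom)
  expect_equal(nrow(rs), cfg$n_genes +
                 cfg$n_chroms * cfg$enhancers_per_chrom)
  # one dip per active promoter and per enhancer, pairwise disjoint
  n_active <- sum(rs$state == "active_promoter")
  expect_equal(nrow(g$truth$planted_dips),
               n_active + cfg$n_chroms * cfg$enhancers_per_chrom)
  d <- g$truth$planted_dips
  expect_true(all(d$end - d$start >= 50))
  red <- reduce_intervals(d)
  expect_equal(nrow(red), nrow(d))
  # mixture proportions form a distribution
  expect_equal(sum(g$truth$mixture), 1)
  # marks: every active promoter carries an H3K4me3 peak over it
  mk <- simulate_mark_tracks(g, cfg)
  act <- rs[rs$state == "active_promoter", ]
  expect_true(all(overlaps_any(act, mk$peaks$H3K4me3)))
  expect_gte(nrow(mk$peaks$H3K4me3), n_active)
})

test_that("genes do not overlap and exon structure is valid", {
  g <- simulate_genome(sim_config(seed = 7))
  spans <- g$models$genes
  red <- reduce_intervals(spans)
  expect_equal(nrow(red), nrow(spans))
  n_ex <- table(g$models$exons$gene_id)
  expect_true(all(n_ex >= 2 & n_ex <= 5))
})

test_that("infeasible packing is an explicit error", {
  expect_error(simulate_genome(sim_config(n_genes = 500L,
                                          chrom_length = 1e6L)),
               "infeasible packing")
})

test_that("methylation levels concentrate around the planted regimes", {
  cfg <- sim_config(seed = 9)
  g <- simulate_genome(cfg)
  mt <- simulate_methylation(g, cfg)
  d <- g$truth$planted_dips[1, , drop = FALSE]
  r <- data.frame(chrom = d$chrom, start = d$start, end = d$end)
  expect_lt(abs(summative_methylation(mt, r, "TI") - cfg$low_ml), 0.05)
  # a background stretch (clear of any gene, island or enhancer) sits at
  # high_ml
  bg <- data.frame(chrom = "chr1", start = 22000L, end = 35000L)
  expect_lt(abs(summative_methylation(mt, bg, "TI") - cfg$high_ml), 0.05)
})

test_that("equal methylation regimes calibrate the downstream t-test", {
  cfg <- sim_config(seed = 10, low_ml = 0.5, high_ml = 0.500001)
  g <- simulate_genome(cfg)
  # force no differential zones by zeroing the causal deltas
  g$truth$causal$delta <- 0
  mt <- simulate_methylation(g, cfg)
  catalog <- annotate_gene_regions(g$models, g$cpg_islands,
                                   g$chrom_lengths)
  rows <- catalog[!is.na(catalog$gene_id) &
                    catalog$category == "whole_gene", ]
  rm_tab <- region_methylation(mt, rows)
  rate <- mean(rm_tab$p_value < 0.05, na.rm = TRUE)
  # ~50 regions: just require no gross inflation
  expect_lte(rate, 0.2)
})

test_that("zero-accessibility new peaks are planted as specified", {
  cfg <- sim_config(seed = 11)
  g <- simulate_genome(cfg)
  mk <- simulate_mark_tracks(g, cfg)
  cells <- simulate_cells(g, mk, cfg)
  np <- names(cells$new_peak_truth)[!is.na(cells$new_peak_truth) &
                                      cells$new_peak_truth == "adaptive"]
  ref_cells <- cells$labels == "reference"
  for (p in np)
    expect_equal(sum(cells$peaks_mat[p, ref_cells]), 0)
})

test_that("noiseless expression recovers every causal category", {
  cfg <- sim_config(seed = 12, expr_noise_frac = 0)
  g <- simulate_genome(cfg)
  meth <- filter_cpgs(simulate_methylation(g, cfg))
  ex <- simulate_expression(g, meth, cfg = cfg)
  bf <- best_fit_expression_model(ex$hyper, ex$expression$log2fc)
  expect_equal(bf$genes$selected_category, ex$causal$category)
  # category regressions are pooled genome-wide, so cross-category
  # prediction order is near- but not exactly perfect even without noise
  expect_gt(bf$C, 0.95)
  # the causal category correlation is -1 under zero noise
  for (k in unique(ex$causal$category)) {
    idx <- ex$causal$category == k
    if (sum(idx) < 3) next
    r <- cor(ex$hyper[cbind(ex$causal$gene_id[idx], k)],
             ex$expression$log2fc[idx])
    expect_lt(r, -0.999)
  }
})
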