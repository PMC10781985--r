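test_that("promoters are 2 kb windows centered on the TSS", {
  gm <- gene_models(
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
               strand = c("+", "+", "-"),
               start = c(10000L, 500L, 8000L),
               end = c(12000L, 2500L, 10001L)),
    data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
               start = c(10000L, 500L, 8000L),
               end = c(12000L, 2500L, 10001L)))
  p <- make_promoters(gm)
  expect_equal(p$start[p$gene_id == "g1"], 9000L)
  expect_equal(p$end[p$gene_id == "g1"], 11000L)
  # left-clip at the chromosome origin
  expect_equal(p$start[p$gene_id == "g2"], 0L)
  expect_equal(p$end[p$gene_id == "g2"], 1500L)
  # minus-strand TSS at end - 1; centering is strand-independent
  expect_equal(p$start[p$gene_id == "g3"], 9000L)
  expect_equal(p$end[p$gene_id == "g3"], 11000L)
  # every promoter contains its TSS base
  tss <- gm$genes$tss[match(p$gene_id, gm$genes$gene_id)]
  expect_true(all(p$start <= tss & tss < p$end))
})

test_that("introns are the gaps between consecutive exons", {
  gm <- toy_models()
  cat0 <- annotate_gene_regions(gm, NULL, c(chr1 = 100000L))
  intr <- cat0[cat0$category == "intron", ]
  expect_equal(intr$start[intr$gene_id == "gA"], 10400L)
  expect_equal(intr$end[intr$gene_id == "gA"], 13000L)
  expect_equal(nrow(intr[intr$gene_id == "gB", ]), 2)
  # single-exon gene yields no introns, without error
  gm1 <- gene_models(
    data.frame(gene_id = "solo", chrom = "chr1", strand = "+",
               start = 100L, end = 300L),
    data.frame(gene_id = "solo", chrom = "chr1", start = 100L,
               end = 300L))
  cat1 <- annotate_gene_regions(gm1, NULL, c(chr1 = 1000L))
  expect_equal(sum(cat1$category == "intron"), 0)
})

test_that("exons and introns partition each gene span exactly", {
  gm <- toy_models()
  cat0 <- annotate_gene_regions(gm, NULL, c(chr1 = 100000L))
  for (g in c("gA", "gB")) {
    rows <- cat0[!is.na(cat0$gene_id) & cat0$gene_id == g &
                   cat0$category %in% c("exon", "intron"), ]
    rows <- rows[order(rows$start), ]
    span <- gm$genes[gm$genes$gene_id == g, ]
    expect_equal(rows$start[1], span$start)
    expect_equal(rows$end[nrow(rows)], span$end)
    expect_true(all(rows$start[-1] == rows$end[-nrow(rows)]))
  }
})

test_that("shores flank islands and shelves flank shores", {
  gm <- toy_models()
  isl <- intervals("chr1", 1000L, 1200L, gene_id = "gA")
  cat0 <- annotate_gene_regions(gm, isl, c(chr1 = 100000L))
  shores <- cat0[cat0$category == "cpg_shore", ]
  shores <- shores[order(shores$start), ]
  expect_equal(shores$start, c(0L, 1200L))
  expect_equal(shores$end, c(1000L, 3200L))
  shelves <- cat0[cat0$category == "cpg_shelf", ]
  expect_equal(sort(shelves$start), c(3200L))
  expect_equal(sort(shelves$end), c(5200L))
  # cpg_inter is the complement of island + shore + shelf
  inter <- cat0[cat0$category == "cpg_inter", ]
  covered <- sum(inter$end - inter$start) +
    sum(shores$end - shores$start) + sum(shelves$end - shelves$start) +
    sum(isl$end - isl$start)
  expect_equal(covered, 100000L)
})

test_that("without islands the CpG taxonomy is all intergenic", {
  gm <- toy_models()
  cat0 <- annotate_gene_regions(gm, NULL, c(chr1 = 100000L))
  expect_equal(sum(cat0$category %in%
                     c("cpg_island", "cpg_shore", "cpg_shelf")), 0)
  inter <- cat0[cat0$category == "cpg_inter", ]
  expect_equal(sum(inter$end - inter$start), 100000L)
})

test_that("UTR categories appear only when provided", {
  gm <- toy_models()
  base <- annotate_gene_regions(gm, NULL, c(chr1 = 100000L))
  expect_false(any(base$category %in% c("utr5", "utr3")))
  utrs <- data.frame(chrom = "chr1", start = c(10000L, 15800L),
                     end = c(10200L, 16000L), gene_id = "gA",
                     category = c("utr5", "utr3"))
  with_utr <- annotate_gene_regions(gm, NULL, c(chr1 = 100000L),
                                    utrs = utrs)
  expect_equal(sum(with_utr$category == "utr5"), 1)
  expect_equal(with_utr$start[with_utr$category == "utr3"], 15800L)
})

test_that("upstream blocks are strand-aware", {
  gm <- toy_models()   # gA on +, tss 10000; gB on -, tss 57999
  cat0 <- annotate_gene_regions(gm, NULL, c(chr1 = 100000L))
  up <- cat0[cat0$category == "upstream_1to5kb", ]
  expect_equal(up$start[up$gene_id == "gA"], 5000L)
  expect_equal(up$end[up$gene_id == "gA"], 9000L)
  expect_equal(up$start[up$gene_id == "gB"], 59000L)
  expect_equal(up$end[up$gene_id == "gB"], 63000L)
})
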