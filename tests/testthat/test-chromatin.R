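test_that("state rules pick out active promoters, enhancers, repression", {
  expect_equal(classify_chromatin_state(c("H3K4me3", "H3K27ac"), TRUE),
               "active_promoter")
  expect_equal(classify_chromatin_state(c("H3K4me1", "H3K27ac"), FALSE,
                                        FALSE),
               "predicted_enhancer")
  expect_equal(classify_chromatin_state("H3K27me3", TRUE), "repressed")
  expect_equal(classify_chromatin_state("H3K27me3", FALSE), "repressed")
  expect_equal(classify_chromatin_state(character(), TRUE),
               "unclassified")
  # H3K4me1 is free at active promoters
  expect_equal(classify_chromatin_state(
    c("H3K4me3", "H3K4me1", "H3K27ac"), TRUE), "active_promoter")
  # strict mode excludes gene-body enhancers
  expect_equal(classify_chromatin_state(c("H3K4me1", "H3K27ac"), FALSE,
                                        TRUE, strict = TRUE),
               "unclassified")
  expect_equal(classify_chromatin_state(c("H3K4me1", "H3K27ac"), FALSE,
                                        TRUE, strict = FALSE),
               "predicted_enhancer")
  expect_error(classify_chromatin_state("H3K9me3", FALSE), "unknown")
})

test_that("state rules match the hand truth table on all 32 inputs", {
  marks <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3")
  for (bits in 0:15) {
    present <- marks[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0]
    for (in_prom in c(FALSE, TRUE)) {
      got <- classify_chromatin_state(present, in_prom)
      ref <- state_truth_table("H3K4me3" %in% present,
                               "H3K4me1" %in% present,
                               "H3K27ac" %in% present,
                               "H3K27me3" %in% present, in_prom)
      expect_equal(got, ref,
                   label = paste("marks:", paste(present, collapse = "+"),
                                 "prom:", in_prom))
    }
  }
})

test_that("state annotation over synthetic peaks reproduces planted truth", {
  cfg <- sim_config(seed = 8, track_noise_lambda = 0)
  g <- simulate_genome(cfg)
  marks <- simulate_mark_tracks(g, cfg)
  rs <- g$truth$region_states
  promoters <- make_promoters(g$models)
  ann <- annotate_states(rs[, c("chrom", "start", "end")], marks$peaks,
                         promoters, g$models$genes)
  mapped <- ifelse(rs$state == "background", "unclassified", rs$state)
  expect_equal(ann$state, mapped)
})

test_that("dip filtering keeps exactly the overlapping peaks", {
  peaks <- intervals("chr1", c(0L, 100L, 200L), c(50L, 150L, 250L),
                     name = c("a", "b", "c"))
  expect_equal(nrow(filter_peaks_by_dips(peaks, peaks[0, ])), 0)
  all_cover <- intervals("chr1", 0L, 300L)
  expect_equal(filter_peaks_by_dips(peaks, all_cover)$name,
               c("a", "b", "c"))
  dip <- intervals("chr1", 120L, 130L)
  expect_equal(filter_peaks_by_dips(peaks, dip)$name, "b")
  # brute-force cross-check on random instances
  set.seed(19)
  for (rep in 1:10) {
    p <- rand_intervals(20); d <- rand_intervals(10)
    got <- filter_peaks_by_dips(p, d)
    ref <- p[sort(unique(brute_overlaps(p, d)$index_a)), ]
    rownames(got) <- rownames(ref) <- NULL
    expect_equal(got, ref)
  }
})

test_that("upset counts partition the anchors exactly", {
  anchors <- intervals("chr1", c(0L, 100L, 200L), c(50L, 150L, 250L))
  f1 <- intervals("chr1", 10L, 20L)
  u <- upset_counts(anchors, list(f = f1))
  expect_equal(u$count[u$combo == "none"], 2L)
  expect_equal(u$count[u$combo == "f"], 1L)
  # disjoint sets all covering every anchor: one full-combination bucket
  u2 <- upset_counts(anchors, list(x = intervals("chr1", 0L, 260L),
                                   y = intervals("chr1", 0L, 260L)))
  expect_equal(u2$combo, "x&y")
  expect_equal(u2$count, 3L)
})

test_that("upset counts equal the exhaustive membership tally", {
  set.seed(29)
  for (rep in 1:5) {
    anchors <- rand_intervals(25)
    fs <- list(A = rand_intervals(8), B = rand_intervals(8),
               C = rand_intervals(8), D = rand_intervals(8))
    got <- upset_counts(anchors, fs)
    ref <- brute_upset(anchors, fs)
    expect_equal(sum(got$count), nrow(anchors))
    for (i in seq_len(nrow(got)))
      expect_equal(got$count[i], ref[[got$combo[i]]],
                   label = got$combo[i])
    expect_equal(nrow(got), length(ref))
  }
})
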