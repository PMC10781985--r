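library(Matrix)

toy_mat <- function(m, genes = NULL) {
  m <- as(Matrix(m, sparse = TRUE), "CsparseMatrix")
  if (!is.null(genes)) rownames(m) <- genes
  m
}

test_that("pseudobulk sums and fractions match a dense loop", {
  m <- toy_mat(rbind(c(1, 0, 2, 0), c(0, 0, 5, 1)), c("g1", "g2"))
  labels <- c("A", "A", "B", "B")
  pb <- pseudobulk(m, labels)
  expect_equal(pb$sums["g1", "A"], 1)
  expect_equal(pb$fractions["g1", "A"], 0.5)
  expect_equal(pb$fractions["g2", "B"], 1)
  expect_error(pseudobulk(m, c("A", "A", "B", NA)), "unlabeled")
  set.seed(53)
  big <- toy_mat(matrix(rpois(200, 0.8), 20, 10),
                 sprintf("g%02d", 1:20))
  lab <- sample(c("x", "y"), 10, replace = TRUE)
  pb2 <- pseudobulk(big, lab)
  dense <- as.matrix(big)
  for (t in unique(lab)) {
    expect_equal(pb2$sums[, t], rowSums(dense[, lab == t, drop = FALSE]))
    expect_equal(pb2$fractions[, t],
                 rowMeans(dense[, lab == t, drop = FALSE] > 0))
  }
})

test_that("identical groups yield no DE genes", {
  set.seed(59)
  m <- toy_mat(matrix(rpois(50 * 200, 1.5), 50, 200),
               sprintf("g%02d", 1:50))
  labels <- rep(c("a", "b"), each = 100)
  de <- de_genes_wilcoxon(m, labels, "a", "b")
  expect_equal(sum(de$is_de), 0)
})

test_that("complete separation is detected with a positive fold change", {
  m <- toy_mat(rbind(c(rep(3, 50), rep(0, 50)),
                     matrix(rpois(20 * 100, 1), 20, 100)),
               c("sep", sprintf("bg%02d", 1:20)))
  labels <- rep(c("a", "b"), each = 50)
  de <- de_genes_wilcoxon(m, labels, "a", "b")
  row <- de[de$gene == "sep", ]
  expect_true(row$is_de)
  expect_gt(row$avg_log2fc, 0)
})

test_that("swapping groups negates fold changes and keeps p-values", {
  set.seed(61)
  m <- toy_mat(matrix(rpois(30 * 120, 1.2), 30, 120),
               sprintf("g%02d", 1:30))
  labels <- rep(c("a", "b"), each = 60)
  d1 <- de_genes_wilcoxon(m, labels, "a", "b")
  d2 <- de_genes_wilcoxon(m, labels, "b", "a")
  expect_equal(d1$avg_log2fc, -d2$avg_log2fc, tolerance = 1e-12)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
})

test_that("genes below the expressed-cell floor are not tested", {
  m <- toy_mat(rbind(c(1, rep(0, 199)), rep(1, 200)), c("rare", "common"))
  labels <- rep(c("a", "b"), each = 100)
  de <- de_genes_wilcoxon(m, labels, "a", "b", min_pct = 0.02)
  expect_false("rare" %in% de$gene)   # 1% in one group only
  expect_true("common" %in% de$gene)
})

test_that("DA logistic LR statistic equals the glm deviance difference", {
  set.seed(67)
  for (rep in 1:5) {
    n <- 80
    acc <- rbinom(n, 1, 0.4)
    grp <- rep(c(1, 0), each = n / 2)
    m <- toy_mat(matrix(acc, 1, n), "pk")
    labels <- ifelse(grp == 1, "a", "b")
    da <- da_peaks_lr(m, labels, "a", "b")
    full <- glm(grp ~ acc, family = binomial)
    null <- glm(grp ~ 1, family = binomial)
    expect_equal(da$lr_stat, null$deviance - full$deviance,
                 tolerance = 1e-8)
  }
})

test_that("DA calls separated peaks and skips empty ones", {
  set.seed(71)
  acc_a <- rbinom(200, 1, 0.9); acc_b <- rbinom(200, 1, 0.05)
  m <- toy_mat(rbind(c(acc_a, acc_b),
                     rep(0, 400),
                     c(rbinom(200, 1, 0.3), rbinom(200, 1, 0.3))),
               c("hot", "dead", "flat"))
  labels <- rep(c("a", "b"), each = 200)
  da <- da_peaks_lr(m, labels, "a", "b")
  expect_false("dead" %in% da$peak)          # accessible in no cell
  hot <- da[da$peak == "hot", ]
  expect_true(hot$is_da)
  expect_gt(hot$avg_log2fc, 0)
  flat <- da[da$peak == "flat", ]
  expect_false(flat$is_da)
})

test_that("new peaks require DA plus a near-silent comparator", {
  da <- data.frame(peak = c("p1", "p2", "p3"),
                   frac_a = c(0.5, 0.5, 0.0),
                   frac_b = c(0.01, 0.05, 0.0),
                   avg_log2fc = c(3, 2, 0),
                   lr_stat = c(50, 50, 0),
                   p_value = c(1e-12, 1e-12, 1),
                   p_bonferroni = c(1e-10, 1e-10, 1),
                   is_da = c(TRUE, TRUE, FALSE),
                   is_new_peak = NA, new_peak_group = NA_character_)
  class(da) <- c("da_result", "data.frame")
  attr(da, "groups") <- c(a = "adaptive", b = "reference")
  out <- find_new_peaks(da)
  expect_equal(out$is_new_peak, c(TRUE, FALSE, FALSE))
  expect_equal(out$new_peak_group, c("adaptive", NA, NA))
})

test_that("gene open-chromatin AUC honors the 5 kb containment window", {
  fr <- matrix(c(0.5, 0.2, 0.4,
                 0.1, 0.3, 0.0), 3, 2,
               dimnames = list(c("at_tss", "near", "far"),
                               c("ref", "adp")))
  peaks <- data.frame(chrom = "chr1",
                      start = c(9900L, 12000L, 16500L),
                      end = c(10100L, 12400L, 16900L))
  gene <- data.frame(chrom = "chr1", tss = 10000L)
  auc <- gene_open_chromatin_auc(fr, peaks, gene, 5000L)
  expect_equal(auc[["ref"]], 0.5 + 0.2)     # far peak excluded
  expect_equal(auc[["adp"]], 0.1 + 0.3)
  # TSS-overlapping peak counts even when not fully contained
  peaks2 <- data.frame(chrom = "chr1", start = c(4000L),
                       end = c(10500L))
  fr2 <- matrix(0.7, 1, 1, dimnames = list("span", "ref"))
  expect_equal(gene_open_chromatin_auc(fr2, peaks2, gene)[["ref"]], 0.7)
  # no qualifying peaks: zero
  gene2 <- data.frame(chrom = "chr2", tss = 10000L)
  expect_equal(unname(gene_open_chromatin_auc(fr, peaks, gene2)),
               c(0, 0))
})

test_that("signature construction applies the top-10% and >=20 rules", {
  mk_de <- function(n, prefix) data.frame(
    gene = sprintf("%s%03d", prefix, seq_len(n)),
    pct_a = 1, pct_b = 0.1,
    avg_log2fc = seq(n, 1) / 10,
    p_value = 1e-9, p_bonferroni = 1e-7, is_de = TRUE)
  profiles <- matrix(1, 400, 2,
                     dimnames = list(c(sprintf("big%03d", 1:200),
                                       sprintf("sml%03d", 1:200)),
                                     c("big", "small")))
  de <- list(big = mk_de(200, "big"), small = mk_de(150, "sml"))
  sig <- build_signature(de, promoter_peak_genes = rownames(profiles),
                         profiles = profiles)
  # 10% of 200 = 20 markers -> retained; 10% of 150 = 15 < 20 -> dropped
  expect_equal(names(sig$markers), "big")
  expect_equal(length(sig$markers$big), 20)
  expect_equal(sig$dropped, "small")
  # markers are the highest-fold-change DEGs
  expect_setequal(sig$markers$big, sprintf("big%03d", 1:20))
  # a configured type removal drops its column before filtering
  de2 <- list(big = mk_de(200, "big"), other = mk_de(300, "sml"))
  sig2 <- build_signature(de2, rownames(profiles), profiles,
                          drop_types = "other")
  expect_equal(names(sig2$markers), "big")
  expect_error(build_signature(list(small = mk_de(150, "sml")),
                               rownames(profiles), profiles),
               "filtered out")
})

test_that("deconvolution recovers exact mixtures and stays on the simplex", {
  set.seed(73)
  sig <- matrix(runif(60, 0.5, 3), 20, 3,
                dimnames = list(sprintf("m%02d", 1:20),
                                c("A", "B", "C")))
  bulk <- as.numeric(sig %*% c(0.5, 0.5, 0))
  p <- deconvolve(sig, setNames(bulk, rownames(sig)))
  expect_equal(unname(p), c(0.5, 0.5, 0), tolerance = 1e-8)
  pure <- deconvolve(sig, setNames(as.numeric(sig[, "A"]),
                                   rownames(sig)))
  expect_equal(unname(pure), c(1, 0, 0), tolerance = 1e-8)
  set.seed(79)
  for (rep in 1:10) {
    w <- c(0.6, 0.3, 0.1)
    noisy <- as.numeric(sig %*% w) * (1 + rnorm(20, 0, 0.05))
    est <- deconvolve(sig, setNames(pmax(noisy, 0), rownames(sig)))
    expect_true(all(est >= 0))
    expect_equal(sum(est), 1, tolerance = 1e-12)
  }
  expect_warning(deconvolve(cbind(sig[, 1], sig[, 1]),
                            setNames(as.numeric(sig[, 1]),
                                     rownames(sig))),
                 "rank-deficient")
})
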