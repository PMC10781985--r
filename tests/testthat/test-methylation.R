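mk_track <- function(pos, numC_g, numT_g, numC_t = numC_g,
                     numT_t = numT_g, chrom = "chr1") {
  meth_track(data.frame(chrom = chrom, pos = pos),
             list(GLOM = list(numC = as.matrix(numC_g),
                              numT = as.matrix(numT_g)),
                  TI = list(numC = as.matrix(numC_t),
                            numT = as.matrix(numT_t))))
}

test_that("coverage filter is strict in every sample of both compartments", {
  tr <- mk_track(pos = c(10L, 20L, 30L),
                 numC_g = cbind(c(3L, 4L, 10L), c(3L, 2L, 10L)),
                 numT_g = cbind(c(2L, 2L, 10L), c(3L, 3L, 10L)))
  # site 1: coverage 5 and 6 -> removed (strict > 5); site 2: 6,5 -> removed
  kept <- filter_cpgs(tr, 5L)
  expect_equal(kept$sites$pos, 30L)
  # coverage 6 everywhere is kept
  tr6 <- mk_track(pos = 1:3 * 10L,
                  numC_g = matrix(3L, 3, 2), numT_g = matrix(3L, 3, 2))
  expect_equal(nrow(filter_cpgs(tr6, 5L)$sites), 3)
  # vacuous filter is the identity
  expect_equal(nrow(filter_cpgs(tr, 0L)$sites), 3)
})

test_that("summative methylation pools counts before dividing", {
  tr <- mk_track(pos = c(10L, 20L),
                 numC_g = matrix(c(3L, 1L), 2, 1),
                 numT_g = matrix(c(1L, 3L), 2, 1))
  r <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(summative_methylation(tr, r, "GLOM"), 0.5)
  # fully methylated
  tr1 <- mk_track(pos = c(10L, 20L),
                  numC_g = matrix(c(4L, 2L), 2, 1),
                  numT_g = matrix(0L, 2, 1))
  expect_equal(summative_methylation(tr1, r, "GLOM"), 1)
  # zero-coverage region yields NA, not 0
  empty <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  expect_true(is.na(summative_methylation(tr, empty, "GLOM")))
})

test_that("summative methylation equals the flat-loop oracle", {
  set.seed(11)
  pos <- sort(sample(0:999, 10))
  tr <- mk_track(pos = pos,
                 numC_g = matrix(rpois(40, 5), 10, 4),
                 numT_g = matrix(rpois(40, 5), 10, 4))
  for (rep in 1:10) {
    s <- sample(0:900, 1)
    r <- data.frame(chrom = "chr1", start = s, end = s + 200L)
    expect_equal(summative_methylation(tr, r, "GLOM"),
                 brute_summative(tr, r, "GLOM"), tolerance = 1e-12)
  }
})

test_that("hyper is the log2 ratio with pseudocount and is antisymmetric", {
  expect_equal(hyper(0.5, 0.5), 0)
  expect_equal(hyper(0.8, 0.2, 0.001), log2(0.801 / 0.201),
               tolerance = 1e-12)
  set.seed(3)
  a <- runif(100); b <- runif(100)
  expect_equal(hyper(a, b), -hyper(b, a), tolerance = 1e-12)
  expect_error(hyper(0.5, 0.5, beta = 0), "positive")
  expect_error(hyper(1.2, 0.5), "\\[0, 1\\]")
})

test_that("hyper is monotone in both arguments", {
  g <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(hyper(g, 0.5)) > 0))
  expect_true(all(diff(hyper(0.5, g)) < 0))
})

test_that("compartment t-test handles degenerate and separated groups", {
  res <- diff_region_methylation(matrix(0.3, 1, 3), matrix(0.3, 1, 3))
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  a <- matrix(c(0.1, 0.11, 0.1, 0.09), 1, 4)
  b <- matrix(c(0.9, 0.91, 0.9, 0.89), 1, 4)
  expect_lt(diff_region_methylation(a, b)$p_value, 1e-4)
})

test_that("null regions reject at close to the nominal rate", {
  set.seed(21)
  n <- 1000
  a <- matrix(rbinom(n * 4, 50, 0.5) / 50, n, 4)
  b <- matrix(rbinom(n * 4, 50, 0.5) / 50, n, 4)
  res <- diff_region_methylation(a, b)
  rate <- mean(res$p_value < 0.05)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("dip calling follows the <=0.4 over >=50 bp rule", {
  win <- function(starts, ml) data.frame(chrom = "chr1", start = starts,
                                         end = starts + 10L, ml = ml)
  # 100 bp at 0.3 flanked by 0.9 -> one dip of exactly 100 bp
  w <- win(seq(0L, 190L, 10L), c(rep(0.9, 5), rep(0.3, 10), rep(0.9, 5)))
  d <- call_methyl_dips(w)
  expect_equal(d, data.frame(chrom = "chr1", start = 50L, end = 150L))
  # everything above threshold -> no dips
  expect_equal(nrow(call_methyl_dips(win(seq(0L, 90L, 10L),
                                         rep(0.5, 10)))), 0)
  # 40 bp below threshold -> too short
  w2 <- win(seq(0L, 120L, 10L), c(rep(0.9, 4), rep(0.3, 4), rep(0.9, 5)))
  expect_equal(nrow(call_methyl_dips(w2)), 0)
  # boundary: ml exactly 0.4 qualifies, exactly 50 bp qualifies
  w3 <- win(seq(0L, 140L, 10L), c(rep(0.9, 5), rep(0.4, 5), rep(0.9, 5)))
  expect_equal(call_methyl_dips(w3)$end - call_methyl_dips(w3)$start, 50L)
})

test_that("dip caller matches the sliding-scan brute force on random tracks", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    w <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = NA_integer_, end = NA_integer_,
                    ml = ifelse(runif(n) < 0.1, NA,
                                round(runif(n), 2)))
    for (ch in unique(w$chrom)) {
      idx <- which(w$chrom == ch)
      # contiguous except for occasional gaps
      starts <- cumsum(c(0L, sample(c(10L, 10L, 10L, 30L),
                                    length(idx) - 1, replace = TRUE)))
      w$start[idx] <- starts
      w$end[idx] <- starts + 10L
    }
    got <- call_methyl_dips(w)
    ref <- brute_dips(w)
    rownames(got) <- rownames(ref) <- NULL
    expect_equal(got, ref)
  }
})

test_that("dips never overlap and are maximal", {
  set.seed(5)
  n <- 200
  w <- data.frame(chrom = "chr1", start = seq(0L, by = 10L,
                                              length.out = n))
  w$end <- w$start + 10L
  w$ml <- round(runif(n), 2)
  d <- call_methyl_dips(w)
  if (nrow(d) > 1)
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  # maximality: the window just outside each dip is above threshold
  for (i in seq_len(nrow(d))) {
    before <- w$ml[w$end == d$start[i]]
    after <- w$ml[w$start == d$end[i]]
    if (length(before)) expect_gt(before, 0.4)
    if (length(after)) expect_gt(after, 0.4)
  }
})

test_that("summative pooling of disjoint parts equals the union", {
  set.seed(17)
  pos <- sort(sample(0:999, 30))
  tr <- mk_track(pos = pos,
                 numC_g = matrix(rpois(120, 6), 30, 4),
                 numT_g = matrix(rpois(120, 6), 30, 4))
  left <- data.frame(chrom = "chr1", start = 0L, end = 500L)
  right <- data.frame(chrom = "chr1", start = 500L, end = 1000L)
  whole <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  cov_of <- function(r) {
    idx <- which(tr$sites$pos >= r$start & tr$sites$pos < r$end)
    sum(tr$compartments$GLOM$numC[idx, ]) +
      sum(tr$compartments$GLOM$numT[idx, ])
  }
  ml_l <- summative_methylation(tr, left, "GLOM")
  ml_r <- summative_methylation(tr, right, "GLOM")
  pooled <- (ml_l * cov_of(left) + ml_r * cov_of(right)) /
    (cov_of(left) + cov_of(right))
  expect_equal(summative_methylation(tr, whole, "GLOM"), pooled,
               tolerance = 1e-12)
})
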