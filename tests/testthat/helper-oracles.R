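# Independent brute-force oracles used across the suite. These are written
# for clarity, not speed, and never share code with the implementation.

# all-pairs quadratic overlap scan (half-open)
brute_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i])
      out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(index_a = integer(),
                                      index_b = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(index_a = m[, 1], index_b = m[, 2])
  df[order(df$index_a, df$index_b), , drop = FALSE]
}

# per-base sliding scan dip caller over a windowed methylation table
brute_dips <- function(windows, max_ml = 0.4, min_len_bp = 50L) {
  out <- list()
  for (ch in sort(unique(windows$chrom))) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    L <- max(w$end)
    low <- rep(FALSE, L)          # per-base "covered by a low window"
    for (i in seq_len(nrow(w)))
      if (!is.na(w$ml[i]) && w$ml[i] <= max_ml)
        low[(w$start[i] + 1):w$end[i]] <- TRUE
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (k in seq_along(r$values))
      if (r$values[k] && r$lengths[k] >= min_len_bp)
        out[[length(out) + 1]] <- data.frame(chrom = ch,
                                             start = starts[k],
                                             end = ends[k])
  }
  if (!length(out)) return(data.frame(chrom = character(),
                                      start = integer(),
                                      end = integer()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# exhaustive membership tally for upset counts
brute_upset <- function(anchors, feature_sets) {
  counts <- list()
  for (i in seq_len(nrow(anchors))) {
    members <- character()
    for (nm in names(feature_sets)) {
      fs <- feature_sets[[nm]]
      hit <- FALSE
      for (j in seq_len(nrow(fs))) {
        if (anchors$chrom[i] == fs$chrom[j] &&
            anchors$start[i] < fs$end[j] &&
            fs$start[j] < anchors$end[i]) { hit <- TRUE; break }
      }
      if (hit) members <- c(members, nm)
    }
    key <- if (!length(members)) "none" else paste(members,
                                                   collapse = "&")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  counts
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Fisher p by full hypergeometric enumeration of tables with the
# observed margins, summing those at most as probable as the observed one
brute_fisher_p <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; r2 <- n01 + n00
  c1 <- n11 + n01; n <- r1 + r2
  prob <- function(k) choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  ks <- max(0, c1 - r2):min(r1, c1)
  p_obs <- prob(n11)
  sum(vapply(ks, prob, numeric(1))[
    vapply(ks, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# O(n^2) pair-counting concordance index
brute_cindex <- function(pred, obs) {
  n <- length(pred); num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    den <- den + 1
    dp <- pred[i] - pred[j]; do <- obs[i] - obs[j]
    if (dp * do > 0) num <- num + 1
    else if (dp == 0 || do == 0) num <- num + 0.5
  }
  num / den
}

# flat-loop accumulation of region-summative methylation
brute_summative <- function(track, region, compartment) {
  cs <- 0; ts <- 0
  m <- track$compartments[[compartment]]
  for (i in seq_len(nrow(track$sites))) {
    if (track$sites$chrom[i] == region$chrom[1] &&
        track$sites$pos[i] >= region$start[1] &&
        track$sites$pos[i] < region$end[1]) {
      cs <- cs + sum(m$numC[i, ])
      ts <- ts + sum(m$numT[i, ])
    }
  }
  if (cs + ts == 0) NA_real_ else cs / (cs + ts)
}

# hand truth table for the chromatin state rules (permissive mode)
state_truth_table <- function(k4me3, k4me1, k27ac, k27me3, in_promoter) {
  if (k4me3 && k27ac && in_promoter) return("active_promoter")
  if (k4me1 && k27ac && !k4me3 && !in_promoter)
    return("predicted_enhancer")
  if (k27me3) return("repressed")
  "unclassified"
}

# small deterministic two-gene model used by several files
toy_models <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), symbol = c("gA", "gB"),
                      chrom = "chr1", strand = c("+", "-"),
                      start = c(10000L, 50000L),
                      end = c(16000L, 58000L))
  exons <- data.frame(gene_id = c("gA", "gA", "gB", "gB", "gB"),
                      chrom = "chr1",
                      start = c(10000L, 13000L, 50000L, 53000L, 56000L),
                      end = c(10400L, 16000L, 51000L, 54000L, 58000L))
  gene_models(genes, exons)
}

# random interval helper
rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L) {
  s <- sample(0:(max_pos - 2L), n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s,
             end = s + sample(1:50, n, replace = TRUE))
}
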