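#' Per-CpG bisulfite count track
#'
#' Holds methylated (`numC`) and unmethylated (`numT`) read counts per CpG
#' site, per sample, per tissue compartment (glomerulus `GLOM` and
#' tubulointerstitium `TI` in the kidney application). Coverage is
#' `numC + numT` by construction.
#'
#' @param sites data.frame with `chrom` and `pos` (0-based CpG position).
#' @param compartments named list; each element is a list with integer
#'   matrices `numC` and `numT` of dimension sites x samples.
#' @return object of class `meth_track`.
#' @export
meth_track <- function(sites, compartments) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)),
            length(names(compartments)) == length(compartments))
  n <- nrow(sites)
  for (cp in names(compartments)) {
    m <- compartments[[cp]]
    stopifnot(all(c("numC", "numT") %in% names(m)),
              nrow(m$numC) == n, nrow(m$numT) == n,
              ncol(m$numC) == ncol(m$numT))
    if (any(m$numC < 0) || any(m$numT < 0))
      stop("negative counts in compartment ", cp)
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  compartments <- lapply(compartments, function(m)
    list(numC = m$numC[ord, , drop = FALSE],
         numT = m$numT[ord, , drop = FALSE]))
  # per-chromosome position index for O(log n) region lookups
  pos_split <- split(sites$pos, sites$chrom)
  offsets <- cumsum(c(0L, vapply(pos_split, length, 1L)))
  names(offsets) <- c(names(pos_split), "_end")
  structure(list(sites = sites, compartments = compartments,
                 pos_split = pos_split, offsets = offsets),
            class = "meth_track")
}

#' @export
print.meth_track <- function(x, ...) {
  cat("meth_track:", nrow(x$sites), "CpG sites;",
      paste0(names(x$compartments), "(",
             vapply(x$compartments, function(m) ncol(m$numC), 1L), ")",
             collapse = ", "), "samples\n")
  invisible(x)
}

#' Coverage filter across all samples
#'
#' Keeps a CpG site only when its coverage exceeds `min_coverage` (strict
#' `>`) in every sample of every compartment.
#'
#' @param track a `meth_track`.
#' @param min_coverage reads; default 5.
#' @return filtered `meth_track` (possibly with zero sites).
#' @export
filter_cpgs <- function(track, min_coverage = 5L) {
  stopifnot(inherits(track, "meth_track"))
  keep <- rep(TRUE, nrow(track$sites))
  for (m in track$compartments) {
    cov <- m$numC + m$numT
    keep <- keep & apply(cov > min_coverage, 1, all)
  }
  meth_track(track$sites[keep, , drop = FALSE],
             lapply(track$compartments, function(m)
               list(numC = m$numC[keep, , drop = FALSE],
                    numT = m$numT[keep, , drop = FALSE])))
}

# row indices of CpG sites inside a half-open region (binary search on the
# sorted per-chromosome position index)
sites_in_region <- function(track, region) {
  ch <- region$chrom[1]
  ps <- track$pos_split[[ch]]
  if (is.null(ps) || !length(ps)) return(integer())
  lo <- findInterval(region$start[1] - 0.5, ps) + 1L
  hi <- findInterval(region$end[1] - 0.5, ps)
  if (hi < lo) return(integer())
  track$offsets[[ch]] + (lo:hi)
}

#' Region-summative methylation level
#'
#' Counts are pooled over all CpGs in the region and over the selected
#' samples before the ratio is taken:
#' `ml = sum(numC) / sum(numC + numT)`. This sum-then-divide pooling, not
#' a mean of per-site ratios, is the defining choice of the statistic.
#'
#' @param track a `meth_track`.
#' @param region single-row interval table.
#' @param compartment compartment name.
#' @param samples optional integer/logical sample selector (default all).
#' @return methylation level in `[0, 1]`, or `NA_real_` when the region
#'   has zero summed coverage (excluded downstream, never reported as 0).
#' @export
summative_methylation <- function(track, region, compartment,
                                  samples = NULL) {
  stopifnot(inherits(track, "meth_track"),
            compartment %in% names(track$compartments))
  idx <- sites_in_region(track, region)
  m <- track$compartments[[compartment]]
  if (is.null(samples)) samples <- seq_len(ncol(m$numC))
  c_sum <- sum(m$numC[idx, samples, drop = FALSE])
  t_sum <- sum(m$numT[idx, samples, drop = FALSE])
  if (c_sum + t_sum == 0) return(NA_real_)
  c_sum / (c_sum + t_sum)
}

#' Relative (hyper-)methylation between compartments
#'
#' `hyper = log2((ml_GLOM + beta) / (ml_TI + beta))` with pseudocount
#' `beta` (default 0.001). Positive values mean greater methylation in the
#' glomerulus, negative in the tubulointerstitium.
#'
#' @param ml_glom,ml_ti methylation levels in `[0, 1]` (vectorized).
#' @param beta pseudocount, strictly positive.
#' @return numeric log2 ratio.
#' @export
hyper <- function(ml_glom, ml_ti, beta = 0.001) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop("beta must be a single positive number")
  if (any(ml_glom < 0 | ml_glom > 1, na.rm = TRUE) ||
      any(ml_ti < 0 | ml_ti > 1, na.rm = TRUE))
    stop("methylation levels must be in [0, 1]")
  log2((ml_glom + beta) / (ml_ti + beta))
}

#' Differential region methylation between two sample groups
#'
#' Per region, a two-sided Welch t-test on the per-sample region
#' methylation levels, with multiple-testing correction across regions.
#' Regions where both groups are constant with equal means get `t = 0`,
#' `p = 1`.
#'
#' @param ml_a,ml_b numeric matrices, regions x samples, of per-sample
#'   region methylation for the two groups (rows aligned).
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @return data.frame `t_stat`, `p_value`, `p_adjusted` per region.
#' @export
diff_region_methylation <- function(ml_a, ml_b,
                                    correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  ml_a <- as.matrix(ml_a); ml_b <- as.matrix(ml_b)
  stopifnot(nrow(ml_a) == nrow(ml_b))
  res <- t(vapply(seq_len(nrow(ml_a)), function(i) {
    x <- ml_a[i, ]; y <- ml_b[i, ]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(c(NA_real_, NA_real_))
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) return(c(0, 1))
      return(c(sign(mean(x) - mean(y)) * Inf, 0))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2)))
  data.frame(t_stat = res[, 1], p_value = res[, 2],
             p_adjusted = stats::p.adjust(res[, 2], method = correction))
}

#' Region methylation summary over a catalog
#'
#' Computes, per catalog region: pooled methylation per compartment, the
#' per-sample levels, the hyper log-ratio, and the Welch test between the
#' two compartments' per-sample levels.
#'
#' @param track a `meth_track` with compartments `GLOM` and `TI` (or the
#'   two names given in `pair`).
#' @param regions interval table (rows are tested regions; extra columns
#'   such as `gene_id`/`category` are carried through).
#' @param beta pseudocount for [hyper()].
#' @param correction multiple-testing correction.
#' @param pair the two compartment names, numerator first.
#' @return `regions` with `ml_<a>`, `ml_<b>`, `hyper`, `t_stat`,
#'   `p_value`, `p_adjusted`.
#' @export
region_methylation <- function(track, regions, beta = 0.001,
                               correction = c("BH", "bonferroni"),
                               pair = c("GLOM", "TI")) {
  correction <- match.arg(correction)
  stopifnot(all(pair %in% names(track$compartments)))
  per_sample <- function(compartment) {
    m <- track$compartments[[compartment]]
    t(vapply(seq_len(nrow(regions)), function(i) {
      idx <- sites_in_region(track, regions[i, ])
      cs <- colSums(m$numC[idx, , drop = FALSE])
      ts <- colSums(m$numT[idx, , drop = FALSE])
      ifelse(cs + ts == 0, NA_real_, cs / (cs + ts))
    }, numeric(ncol(m$numC))))
  }
  ml_pool <- function(compartment) vapply(seq_len(nrow(regions)),
    function(i) summative_methylation(track, regions[i, ], compartment),
    numeric(1))
  a <- ml_pool(pair[1]); b <- ml_pool(pair[2])
  test <- diff_region_methylation(per_sample(pair[1]), per_sample(pair[2]),
                                  correction = correction)
  out <- regions
  out[[paste0("ml_", pair[1])]] <- a
  out[[paste0("ml_", pair[2])]] <- b
  out$hyper <- hyper(a, b, beta = beta)
  cbind(out, test)
}

#' Pooled methylation in fixed windows
#'
#' Pools counts across all samples of one compartment into contiguous
#' fixed-width windows. Only windows containing at least one CpG are
#' returned; CpG-free windows therefore appear as gaps, which break dip
#' runs (a dip is only as long as its CpG support).
#'
#' @param track a `meth_track`.
#' @param compartment compartment name (default `"TI"`, where regulatory
#'   methylation dips are called in the kidney analysis).
#' @param window_bp window width in bp.
#' @return interval table with `ml`.
#' @export
windowed_methylation <- function(track, compartment = "TI",
                                 window_bp = 10L) {
  stopifnot(inherits(track, "meth_track"),
            compartment %in% names(track$compartments))
  m <- track$compartments[[compartment]]
  win <- track$sites$pos %/% window_bp
  key <- paste(track$sites$chrom, win)
  cs <- rowSums(m$numC); ts <- rowSums(m$numT)
  agg <- stats::aggregate(cbind(cs, ts),
                          by = list(chrom = track$sites$chrom, win = win),
                          FUN = sum)
  out <- intervals(agg$chrom, agg$win * window_bp,
                   (agg$win + 1L) * window_bp,
                   ml = ifelse(agg$cs + agg$ts == 0, NA_real_,
                               agg$cs / (agg$cs + agg$ts)))
  sort_intervals(out)
}

#' Call methylation dips
#'
#' A dip is a maximal run of contiguous windows whose methylation is at or
#' below `max_ml`, reported only when the merged run spans at least
#' `min_len_bp`. Windows with `NA` methylation, or gaps between
#' non-adjacent windows, terminate a run.
#'
#' @param windows interval table with `ml` (see [windowed_methylation()]).
#' @param max_ml methylation ceiling (default 0.4).
#' @param min_len_bp minimum dip span (default 50 bp).
#' @return interval table of dips, sorted; dips never overlap.
#' @export
call_methyl_dips <- function(windows, max_ml = 0.4, min_len_bp = 50L) {
  validate_intervals(windows)
  stopifnot("ml" %in% names(windows))
  w <- sort_intervals(windows)
  out <- list()
  for (ch in unique(w$chrom)) {
    v <- w[w$chrom == ch, , drop = FALSE]
    ok <- !is.na(v$ml) & v$ml <= max_ml
    run_start <- NA_integer_; run_end <- NA_integer_
    flush <- function() {
      if (!is.na(run_start) && run_end - run_start >= min_len_bp)
        out[[length(out) + 1]] <<- data.frame(chrom = ch,
                                              start = run_start,
                                              end = run_end)
    }
    for (i in seq_len(nrow(v))) {
      if (ok[i]) {
        if (!is.na(run_end) && v$start[i] == run_end) {
          run_end <- v$end[i]
        } else {
          flush()
          run_start <- v$start[i]; run_end <- v$end[i]
        }
      } else {
        flush()
        run_start <- NA_integer_; run_end <- NA_integer_
      }
    }
    flush()
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  sort_intervals(res)
}
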