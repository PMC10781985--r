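#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open `[start, end)`, the BED convention, which
#' is the package's internal coordinate system throughout. Extra columns are
#' preserved.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"`.
#' @param ... further equal-length columns carried along.
#' @return a `data.frame` with columns `chrom`, `start`, `end` (and extras).
#' @export
intervals <- function(chrom, start, end, strand = NULL, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("interval chrom must be non-empty")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("intervals must satisfy 0 <= start < end (half-open)")
  invisible(df)
}

#' Convert an interval table to GRanges (internal)
#'
#' Shifts to the 1-based inclusive convention GenomicRanges uses.
#' @noRd
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

#' All overlapping pairs between two interval sets
#'
#' Reports `(index_a, index_b)` for every pair sharing at least one base
#' under half-open semantics; adjacency (`end == start`) does not count.
#' Pairs are sorted by `index_a`, then `index_b`.
#'
#' @param a,b interval tables (see [intervals()]).
#' @return data.frame with columns `index_a`, `index_b`.
#' @export
overlap_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(index_a = integer(), index_b = integer()))
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      ignore.strand = TRUE)
  out <- data.frame(index_a = S4Vectors::queryHits(hits),
                    index_b = S4Vectors::subjectHits(hits))
  out[order(out$index_a, out$index_b), , drop = FALSE]
}

#' Logical overlap indicator for set `a` against set `b`
#' @return logical vector over rows of `a`: does the row overlap any `b`?
#' @export
overlaps_any <- function(a, b) {
  idx <- overlap_intervals(a, b)
  seq_len(nrow(a)) %in% idx$index_a
}

#' Merge overlapping or bookended intervals within a set
#' @param df interval table.
#' @return interval table of the reduced set, sorted by (chrom, start, end).
#' @export
reduce_intervals <- function(df) {
  validate_intervals(df)
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges(df), ignore.strand = TRUE)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  sort_intervals(out)
}

#' Subtract interval set `b` from interval set `a`
#' @return interval table covering the bases of `a` not covered by `b`.
#' @export
setdiff_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0) return(reduce_intervals(a))
  gr <- GenomicRanges::setdiff(as_granges(a), as_granges(b),
                               ignore.strand = TRUE)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  sort_intervals(out)
}

#' Deterministic (chrom, start, end) sort
#' @noRd
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
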