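#' Rule-based chromatin state from mark combinations
#'
#' States follow the mark logic used throughout the kidney landscape
#' analysis, applied in order:
#' \enumerate{
#'   \item H3K4me3+ and H3K27ac+ inside a promoter: `active_promoter`
#'     (H3K4me1 free either way);
#'   \item H3K4me1+ and H3K27ac+, H3K4me3- and outside promoters:
#'     `predicted_enhancer` (with `strict = TRUE` additionally outside
#'     gene bodies, the extragenic-only reading);
#'   \item H3K27me3+ and neither of the above: `repressed`;
#'   \item otherwise `unclassified`.
#' }
#' The four outcomes are mutually exclusive and exhaustive.
#'
#' @param marks_present character vector of present marks, subset of
#'   `c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3")`.
#' @param in_promoter,in_gene_body location flags.
#' @param strict require enhancers to be extragenic?
#' @return one of `"active_promoter"`, `"predicted_enhancer"`,
#'   `"repressed"`, `"unclassified"`.
#' @export
classify_chromatin_state <- function(marks_present, in_promoter,
                                     in_gene_body = FALSE,
                                     strict = FALSE) {
  known <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3")
  if (length(setdiff(marks_present, known)))
    stop("unknown mark: ",
         paste(setdiff(marks_present, known), collapse = ", "))
  has <- function(m) m %in% marks_present
  if (has("H3K4me3") && has("H3K27ac") && in_promoter)
    return("active_promoter")
  if (has("H3K4me1") && has("H3K27ac") && !has("H3K4me3") &&
      !in_promoter && (!strict || !in_gene_body))
    return("predicted_enhancer")
  if (has("H3K27me3"))
    return("repressed")
  "unclassified"
}

#' Annotate chromatin states over a set of anchor regions
#'
#' For each anchor (typically an ATAC peak), mark presence is defined as
#' at least one base of overlap with that mark's peak set, location flags
#' from overlap with promoters/gene bodies, and the state from
#' [classify_chromatin_state()].
#'
#' @param anchors interval table of anchor regions.
#' @param mark_peaks named list of interval tables, one per histone mark.
#' @param promoters,gene_bodies interval tables.
#' @param dips optional interval table of methylation dips; sets `has_dip`.
#' @param strict passed to [classify_chromatin_state()].
#' @return `anchors` with logical mark columns, `in_promoter`,
#'   `in_gene_body`, `has_dip`, and `state`.
#' @export
annotate_states <- function(anchors, mark_peaks, promoters, gene_bodies,
                            dips = NULL, strict = FALSE) {
  validate_intervals(anchors)
  out <- anchors
  marks <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3")
  for (m in marks) {
    pk <- mark_peaks[[m]]
    out[[m]] <- if (is.null(pk) || !nrow(pk)) rep(FALSE, nrow(anchors))
      else overlaps_any(anchors, pk)
  }
  out$in_promoter <- overlaps_any(anchors, promoters)
  out$in_gene_body <- overlaps_any(anchors, gene_bodies)
  out$has_dip <- if (is.null(dips) || !nrow(dips))
    rep(FALSE, nrow(anchors)) else overlaps_any(anchors, dips)
  out$state <- vapply(seq_len(nrow(out)), function(i)
    classify_chromatin_state(marks[c(out$H3K4me3[i], out$H3K4me1[i],
                                     out$H3K27ac[i], out$H3K27me3[i])],
                             out$in_promoter[i], out$in_gene_body[i],
                             strict = strict),
    character(1))
  out
}

#' Keep peaks overlapping methylation dips
#'
#' @param peaks,dips interval tables.
#' @return the subset of `peaks` with at least 1 bp of dip overlap, input
#'   order preserved.
#' @export
filter_peaks_by_dips <- function(peaks, dips) {
  peaks[overlaps_any(peaks, dips), , drop = FALSE]
}

#' Intersection (upset) counts of anchor peaks against feature sets
#'
#' Each anchor peak is assigned the exact combination of feature sets it
#' overlaps; counts over combinations sum to the number of anchors. The
#' combination key joins overlapping set names with `"&"` in the order of
#' `feature_sets`; anchors overlapping nothing get key `"none"`.
#'
#' @param anchors interval table.
#' @param feature_sets named list of interval tables.
#' @return data.frame `combo`, `count`, sorted by decreasing count.
#' @export
upset_counts <- function(anchors, feature_sets) {
  stopifnot(length(feature_sets) >= 1, !is.null(names(feature_sets)))
  member <- vapply(feature_sets, function(fs)
    if (is.null(fs) || !nrow(fs)) rep(FALSE, nrow(anchors))
    else overlaps_any(anchors, fs),
    logical(nrow(anchors)))
  member <- matrix(member, nrow = nrow(anchors),
                   dimnames = list(NULL, names(feature_sets)))
  combo <- apply(member, 1, function(row) {
    nm <- names(feature_sets)[row]
    if (!length(nm)) "none" else paste(nm, collapse = "&")
  })
  tab <- table(combo)
  out <- data.frame(combo = names(tab), count = as.integer(tab),
                    row.names = NULL)
  out[order(-out$count, out$combo), , drop = FALSE]
}
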