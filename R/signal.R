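#' Per-base signal track backed by run-length encoding
#'
#' Stores one nonnegative per-base value per chromosome (coverage-style
#' signal for a histone mark, ATAC, or a DNA methylation fraction) as
#' `S4Vectors::Rle` vectors.
#'
#' @param values interval table with a `value` column (bedGraph layout);
#'   later rows overwrite earlier rows where they overlap.
#' @param chrom_lengths named integer vector; bases not covered by any
#'   interval are 0.
#' @param mark label, e.g. `"H3K4me3"`, `"ATAC"`, `"DNAm"`.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values, chrom_lengths, mark = "signal") {
  validate_intervals(values)
  stopifnot("value" %in% names(values), all(values$value >= 0),
            !is.null(names(chrom_lengths)))
  if (any(values$end > chrom_lengths[values$chrom]))
    stop("signal interval beyond chromosome end")
  rles <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    rows <- which(values$chrom == ch)
    for (i in rows)
      v[(values$start[i] + 1):values$end[i]] <- values$value[i]
    S4Vectors::Rle(v)
  })
  names(rles) <- names(chrom_lengths)
  structure(list(values = rles,
                 chrom_lengths = chrom_lengths,
                 mark = mark),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track [", x$mark, "]: ",
      paste0(names(x$chrom_lengths), ":", x$chrom_lengths,
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Area under the signal over a region
#'
#' The AUC of a region is the sum of its per-base signal; with
#' `normalize = TRUE` (the default) it is divided by the region length,
#' giving a per-base density that is comparable across regions of
#' different widths.
#'
#' @param track a `signal_track`.
#' @param region single-row interval table (or list with `chrom`, `start`,
#'   `end`).
#' @param normalize divide by region width?
#' @return numeric scalar.
#' @export
region_auc <- function(track, region, normalize = TRUE) {
  stopifnot(inherits(track, "signal_track"))
  chrom <- region$chrom[1]; start <- region$start[1]; end <- region$end[1]
  if (is.na(start) || start >= end) stop("zero-length region")
  rle <- track$values[[chrom]]
  if (is.null(rle)) stop("unknown chromosome: ", chrom)
  start <- max(start, 0L)
  end <- min(end, track$chrom_lengths[[chrom]])
  s <- sum(S4Vectors::window(rle, start + 1L, end))
  if (normalize) s / (region$end[1] - region$start[1]) else s
}

#' Per-gene AUC peak/dip filter
#'
#' For each region unit of a gene, the per-base signal density is compared
#' with the density over the whole gene span. In `peak` mode a unit is
#' called a peak when its density is strictly greater than the gene
#' average; in `dip` mode (used for methylation) it is called a dip when
#' strictly smaller. Ties are never called.
#'
#' @param track a `signal_track`.
#' @param gene single row of a gene table (with `chrom`, `start`, `end`).
#' @param units interval table of the gene's region units (see
#'   [gene_region_units()]).
#' @param mode `"peak"` or `"dip"`.
#' @param normalize compare per-base densities (default) rather than raw
#'   summed AUC.
#' @return `units` with columns `auc`, `gene_auc`, `called` (logical).
#' @export
gisch_filter <- function(track, gene, units, mode = c("peak", "dip"),
                         normalize = TRUE) {
  mode <- match.arg(mode)
  gene_auc <- region_auc(track, gene, normalize = normalize)
  auc <- vapply(seq_len(nrow(units)), function(i)
    region_auc(track, units[i, ], normalize = normalize), numeric(1))
  called <- if (mode == "peak") auc > gene_auc else auc < gene_auc
  out <- units
  out$auc <- auc
  out$gene_auc <- gene_auc
  out$called <- called
  out
}

#' Read a bedGraph file into an interval table
#'
#' Lines are sorted on read; no header is expected (track lines starting
#' with `track` or `#` are skipped).
#' @param path file path.
#' @return interval table with a `value` column.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  df <- data.frame(chrom = as.character(dt[[1]]),
                   start = as.integer(dt[[2]]),
                   end = as.integer(dt[[3]]),
                   value = as.numeric(dt[[4]]),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end <= df$start))
    stop("non-positive interval width in ", path,
         " (is the file 1-based?)")
  sort_intervals(df)
}

#' Write an interval table as bedGraph
#' @param df interval table with `value`.
#' @param path output path.
#' @param header optional comment lines (written with a leading `#`).
#' @export
write_bedgraph <- function(df, path, header = NULL) {
  writeLines(if (is.null(header)) character() else paste0("# ", header),
             path)
  data.table::fwrite(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
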