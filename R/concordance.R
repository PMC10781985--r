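#' Cohen's kappa for two binary codings
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginals. When both vectors are
#' constant, chance agreement is 1 and the formula is taken in the limit:
#' identical constants give 1, differing constants give -1 (flagged as
#' degenerate via the `"degenerate"` attribute).
#'
#' @param labels_a,labels_b binary (0/1 or logical) vectors, equal length
#'   >= 2.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  a <- as.integer(as.logical(labels_a))
  b <- as.integer(as.logical(labels_b))
  stopifnot(length(a) == length(b), length(a) >= 2,
            !anyNA(a), !anyNA(b))
  p_o <- mean(a == b)
  p_e <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # both codings constant: chance agreement degenerates; take the limit
    # convention (identical constants 1, differing constants -1)
    k <- if (all(a == b)) 1 else -1
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Code a gene's region units as binary peak/dip vectors per technology
#'
#' Takes the per-technology AUC-filter outputs for one gene (all over the
#' identical unit list) and returns one position-sorted binary vector per
#' technology.
#'
#' @param gisch_calls named list of [gisch_filter()] results for one gene;
#'   every element must describe the same units.
#' @return data.frame: unit columns (`chrom`, `start`, `end`, `category`)
#'   plus one 0/1 column per technology, rows sorted by position.
#' @export
code_gene_regions <- function(gisch_calls) {
  stopifnot(length(gisch_calls) >= 1, !is.null(names(gisch_calls)))
  ref <- gisch_calls[[1]]
  if (nrow(ref) < 2)
    stop("gene has fewer than 2 region units; excluded from coding")
  key <- function(df) paste(df$chrom, df$start, df$end, df$category)
  ord <- order(ref$chrom, ref$start, ref$end, ref$category)
  out <- ref[ord, c("chrom", "start", "end", "category"), drop = FALSE]
  rownames(out) <- NULL
  for (tech in names(gisch_calls)) {
    g <- gisch_calls[[tech]]
    if (!setequal(key(g), key(ref)) || nrow(g) != nrow(ref))
      stop("technologies coded over different unit lists")
    out[[tech]] <- as.integer(g$called[match(key(out), key(g))])
  }
  out
}

#' Per-gene kappa between two technologies
#'
#' @param coding output of [code_gene_regions()].
#' @param tech_a,tech_b column names of the two technologies.
#' @return list: `kappa`, `n_units`, `table` (2x2 contingency,
#'   rows = `tech_a` 1/0, cols = `tech_b` 1/0), `degenerate`.
#' @export
kappa_between <- function(coding, tech_a, tech_b) {
  a <- coding[[tech_a]]; b <- coding[[tech_b]]
  k <- cohens_kappa(a, b)
  tab <- table(factor(a, c(1, 0)), factor(b, c(1, 0)))
  list(kappa = as.numeric(k), n_units = length(a), table = tab,
       degenerate = isTRUE(attr(k, "degenerate")))
}

#' Genome-wide association between two binary feature tracks
#'
#' Two-sided Fisher's exact test on the 2x2 co-occurrence table of two
#' binary flags over genome units (fixed-width bins or region units). The
#' odds ratio is the cross-product ratio; when both off-diagonal cells are
#' zero (perfect association) it is `Inf`, and when any single cell is
#' zero the Haldane 0.5 correction is used for reporting (the p-value is
#' always from the uncorrected table). Degenerate margins (a flag constant
#' over all units) give `p = 1` and an `NA` odds ratio.
#'
#' @param flags_a,flags_b binary vectors of equal length.
#' @return list: `odds_ratio`, `p_value`, `table`.
#' @export
fisher_association <- function(flags_a, flags_b) {
  a <- as.integer(as.logical(flags_a))
  b <- as.integer(as.logical(flags_b))
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(factor(a, c(1, 0)), factor(b, c(1, 0)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  n11 <- tab[1, 1]; n10 <- tab[1, 2]; n01 <- tab[2, 1]; n00 <- tab[2, 2]
  or <- if (n10 == 0 && n01 == 0) {
    Inf
  } else if (any(tab == 0)) {
    ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
  } else {
    (n11 * n00) / (n10 * n01)
  }
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Bin the genome into fixed-width units
#' @param chrom_lengths named integer vector.
#' @param bin_bp bin width (default 1 kb); the last bin of a chromosome is
#'   clipped at its end.
#' @return interval table.
#' @export
genome_bins <- function(chrom_lengths, bin_bp = 1000L) {
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0L, chrom_lengths[[ch]] - 1L, by = bin_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_bp, chrom_lengths[[ch]]))
  })
  do.call(rbind, out)
}

#' Summary of per-gene kappa values
#'
#' @param kappas numeric vector of per-gene kappa values.
#' @return list: `G_T` (unweighted mean kappa across genes) and `bands`,
#'   counts per agreement band (`<0`, `[0,0.2)`, `[0.2,0.4)`, `[0.4,0.6)`,
#'   `[0.6,0.8)`, `[0.8,1]`).
#' @export
kappa_summary <- function(kappas) {
  stopifnot(length(kappas) >= 1, !anyNA(kappas))
  cuts <- cut(kappas, breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf),
              right = FALSE,
              labels = c("<0", "[0,0.2)", "[0.2,0.4)", "[0.4,0.6)",
                         "[0.6,0.8)", "[0.8,1]"))
  list(G_T = mean(kappas), bands = table(cuts))
}
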