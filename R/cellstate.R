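#' Pseudobulk aggregation of a cell-by-feature matrix
#'
#' @param mat sparse or dense nonnegative matrix, features x cells.
#' @param labels cell-type label per cell (no NAs).
#' @return list: `sums` (features x types summed counts) and `fractions`
#'   (features x types fraction of cells with count > 0).
#' @export
pseudobulk <- function(mat, labels) {
  stopifnot(ncol(mat) == length(labels))
  if (anyNA(labels)) stop("unlabeled cells are not allowed")
  labels <- as.character(labels)
  types <- sort(unique(labels))
  if (any(table(labels)[types] == 0)) stop("empty cell type")
  sums <- vapply(types, function(t)
    Matrix::rowSums(mat[, labels == t, drop = FALSE]),
    numeric(nrow(mat)))
  fractions <- vapply(types, function(t) {
    sub <- mat[, labels == t, drop = FALSE]
    Matrix::rowSums(sub > 0) / ncol(sub)
  }, numeric(nrow(mat)))
  dimnames(sums) <- dimnames(fractions) <- list(rownames(mat), types)
  list(sums = sums, fractions = fractions)
}

#' Log-normalize counts to a fixed per-cell total
#'
#' Counts are scaled so every cell sums to `scale_factor` (default
#' 10,000), then `log1p`-transformed; the conventional preprocessing for
#' rank-based single-cell tests. Cells with zero total are left at zero.
#' @param mat features x cells count matrix.
#' @param scale_factor target per-cell total.
#' @return matrix of the same class.
#' @export
lognormalize <- function(mat, scale_factor = 1e4) {
  totals <- Matrix::colSums(mat)
  totals[totals == 0] <- 1
  scaled <- mat %*% Matrix::Diagonal(x = scale_factor / totals)
  if (methods::is(scaled, "sparseMatrix")) {
    scaled@x <- log1p(scaled@x)
    scaled
  } else {
    log1p(as.matrix(scaled))
  }
}

#' Differential expression by Wilcoxon rank-sum test
#'
#' Genes expressed (count > 0) in more than `min_pct` of cells of at least
#' one group are tested on log-normalized counts with a two-sided
#' rank-sum test; Bonferroni correction is applied across tested genes.
#' `avg_log2fc = log2((mean_a + eps) / (mean_b + eps))` over normalized
#' expression; positive means higher in `group_a`. Genes expressed in
#' neither group are skipped, not tested.
#'
#' @param mat features x cells count matrix (genes).
#' @param labels cell labels.
#' @param group_a,group_b labels of the two compared groups.
#' @param alpha Bonferroni-corrected significance level.
#' @param min_pct minimum expressed-cell fraction (strict `>`) in at least
#'   one group.
#' @param min_abs_log2fc optional fold-change filter applied on top of the
#'   p-value rule (e.g. 0.25); `NULL` disables it.
#' @param eps pseudocount inside the fold change.
#' @return data.frame per tested gene: `gene`, `pct_a`, `pct_b`,
#'   `avg_log2fc`, `p_value`, `p_bonferroni`, `is_de`.
#' @export
de_genes_wilcoxon <- function(mat, labels, group_a, group_b,
                              alpha = 0.05, min_pct = 0.02,
                              min_abs_log2fc = NULL, eps = 0.001) {
  labels <- as.character(labels)
  ca <- which(labels == group_a); cb <- which(labels == group_b)
  stopifnot(length(ca) >= 3, length(cb) >= 3)
  norm <- lognormalize(mat)
  pct_a <- Matrix::rowSums(mat[, ca, drop = FALSE] > 0) / length(ca)
  pct_b <- Matrix::rowSums(mat[, cb, drop = FALSE] > 0) / length(cb)
  tested <- which((pct_a > min_pct | pct_b > min_pct) &
                    (pct_a > 0 | pct_b > 0))
  if (!length(tested))
    return(data.frame(gene = character(), pct_a = numeric(),
                      pct_b = numeric(), avg_log2fc = numeric(),
                      p_value = numeric(), p_bonferroni = numeric(),
                      is_de = logical()))
  na <- as.matrix(norm[tested, ca, drop = FALSE])
  nb <- as.matrix(norm[tested, cb, drop = FALSE])
  p <- vapply(seq_along(tested), function(i)
    suppressWarnings(stats::wilcox.test(na[i, ], nb[i, ])$p.value),
    numeric(1))
  lfc <- log2((rowMeans(na) + eps) / (rowMeans(nb) + eps))
  p_bonf <- pmin(p * length(tested), 1)
  is_de <- p_bonf < alpha
  if (!is.null(min_abs_log2fc)) is_de <- is_de & abs(lfc) > min_abs_log2fc
  gene <- if (is.null(rownames(mat))) as.character(tested) else
    rownames(mat)[tested]
  data.frame(gene = gene, pct_a = pct_a[tested], pct_b = pct_b[tested],
             avg_log2fc = unname(lfc), p_value = p,
             p_bonferroni = p_bonf, is_de = is_de, row.names = NULL)
}

#' Differential accessibility by logistic-regression likelihood-ratio test
#'
#' Accessibility is binarized per cell (count > 0, "possessing open
#' chromatin"). Per peak, group membership is regressed on the binary
#' accessibility indicator and compared with the intercept-only model by a
#' 1-df likelihood-ratio chi-square. With a single binary predictor the LR
#' statistic has the closed 2x2 G-test form, which is what is computed.
#' Bonferroni correction is applied across tested peaks;
#' `avg_log2fc = log2((frac_a + eps) / (frac_b + eps))`, positive meaning
#' greater open chromatin in `group_a`. A peak is differentially
#' accessible (DA) when the corrected p-value is below `alpha` and
#' `|avg_log2fc| > 0`. Peaks accessible in no cell are skipped.
#'
#' @inheritParams de_genes_wilcoxon
#' @param peaks optional interval table aligned to the matrix rows; its
#'   columns are carried into the result.
#' @return data.frame of class `da_result`: `peak`, optional coordinates,
#'   `frac_a`, `frac_b`, `avg_log2fc`, `lr_stat`, `p_value`,
#'   `p_bonferroni`, `is_da`, `is_new_peak` (NA until
#'   [find_new_peaks()]), `new_peak_group`.
#' @export
da_peaks_lr <- function(mat, labels, group_a, group_b, alpha = 0.05,
                        eps = 0.001, peaks = NULL) {
  labels <- as.character(labels)
  ca <- which(labels == group_a); cb <- which(labels == group_b)
  stopifnot(length(ca) >= 3, length(cb) >= 3)
  bin <- mat > 0
  k_a <- Matrix::rowSums(bin[, ca, drop = FALSE])
  k_b <- Matrix::rowSums(bin[, cb, drop = FALSE])
  tested <- which(k_a + k_b > 0)
  n_a <- length(ca); n_b <- length(cb)
  ka <- k_a[tested]; kb <- k_b[tested]
  # LR statistic of logistic regression (group ~ accessibility) vs the
  # intercept-only null: the 2x2 G statistic.
  g_cell <- function(o, e) ifelse(o == 0, 0, 2 * o * log(o / e))
  n <- n_a + n_b
  k <- ka + kb
  stat <- g_cell(ka, k * n_a / n) + g_cell(kb, k * n_b / n) +
    g_cell(n_a - ka, (n - k) * n_a / n) +
    g_cell(n_b - kb, (n - k) * n_b / n)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  frac_a <- ka / n_a; frac_b <- kb / n_b
  lfc <- log2((frac_a + eps) / (frac_b + eps))
  p_bonf <- pmin(p * length(tested), 1)
  out <- data.frame(peak = if (is.null(rownames(mat)))
    as.character(tested) else rownames(mat)[tested],
    frac_a = frac_a, frac_b = frac_b, avg_log2fc = lfc,
    lr_stat = stat, p_value = p, p_bonferroni = p_bonf,
    is_da = p_bonf < alpha & abs(lfc) > 0,
    is_new_peak = NA, new_peak_group = NA_character_,
    row.names = NULL)
  if (!is.null(peaks)) {
    out <- cbind(peaks[tested, c("chrom", "start", "end"), drop = FALSE],
                 out)
    rownames(out) <- NULL
  }
  attr(out, "groups") <- c(a = group_a, b = group_b)
  class(out) <- c("da_result", "data.frame")
  out
}

#' Flag new peaks among DA peaks
#'
#' A new peak is a DA peak whose down-group (the comparator cell state)
#' has strictly fewer than `threshold` of its cells with open chromatin:
#' chromatin newly opened in the up-group.
#'
#' @param da a `da_result` from [da_peaks_lr()].
#' @param threshold comparator accessible-cell fraction bound (default
#'   0.02).
#' @return `da` with `is_new_peak` and `new_peak_group` filled in.
#' @export
find_new_peaks <- function(da, threshold = 0.02) {
  stopifnot(inherits(da, "da_result"))
  groups <- attr(da, "groups")
  up_a <- da$avg_log2fc > 0
  comparator <- ifelse(up_a, da$frac_b, da$frac_a)
  da$is_new_peak <- da$is_da & comparator < threshold
  da$new_peak_group <- ifelse(da$is_new_peak,
                              ifelse(up_a, groups[["a"]], groups[["b"]]),
                              NA_character_)
  da
}

#' Gene-level open-chromatin AUC around the TSS
#'
#' Sums per-type accessible-cell fractions over the peaks fully contained
#' in the window `[tss - window_bp, tss + window_bp]`, always including
#' any peak overlapping the TSS base itself. Genes with no qualifying
#' peak score 0.
#'
#' @param fractions peaks x types matrix of accessible-cell fractions
#'   (see [pseudobulk()]).
#' @param peaks interval table aligned to `fractions` rows.
#' @param gene one gene-table row (needs `chrom`, `tss`).
#' @param window_bp half-window around the TSS (default 5000).
#' @return named numeric vector, one AUC per cell type.
#' @export
gene_open_chromatin_auc <- function(fractions, peaks, gene,
                                    window_bp = 5000L) {
  tss <- gene$tss[1]; chrom <- gene$chrom[1]
  same <- peaks$chrom == chrom
  contained <- same & peaks$start >= tss - window_bp &
    peaks$end <= tss + window_bp
  at_tss <- same & peaks$start <= tss & peaks$end > tss
  qual <- contained | at_tss
  if (!any(qual)) {
    z <- rep(0, ncol(fractions)); names(z) <- colnames(fractions)
    return(z)
  }
  colSums(fractions[qual, , drop = FALSE])
}

#' Build a marker-gene signature matrix
#'
#' Per cell type: the top `top_fraction` of its marker DEGs (ranked by
#' decreasing fold change) is intersected with the genes carrying a
#' promoter peak in at least one active histone mark; the type is retained
#' only when at least `min_markers` markers survive. The signature value
#' is the type's pseudobulk profile over the union of retained markers.
#'
#' @param de_tables named list (one per cell type) of DE tables (from
#'   [de_genes_wilcoxon()], the type vs rest); only rows with
#'   `is_de & avg_log2fc > 0` count as marker DEGs.
#' @param promoter_peak_genes character vector of genes with a promoter
#'   peak in H3K27ac, H3K4me1 or H3K4me3.
#' @param profiles features x types matrix of reference expression
#'   profiles (e.g. pseudobulk mean normalized expression).
#' @param top_fraction fraction of each type's marker DEGs taken (default
#'   0.10).
#' @param min_markers minimum surviving markers to retain a type.
#' @param drop_types types removed a priori (mirrors removing clusters
#'   with confounded signatures).
#' @return list of class `signature`: `signature` (markers x retained
#'   types), `markers` (named list per type), `dropped` (types filtered
#'   out).
#' @export
build_signature <- function(de_tables, promoter_peak_genes, profiles,
                            top_fraction = 0.10, min_markers = 20L,
                            drop_types = NULL) {
  stopifnot(!is.null(names(de_tables)))
  de_tables <- de_tables[setdiff(names(de_tables), drop_types)]
  markers <- list()
  for (ty in names(de_tables)) {
    tab <- de_tables[[ty]]
    tab <- tab[tab$is_de & tab$avg_log2fc > 0, , drop = FALSE]
    tab <- tab[order(-tab$avg_log2fc), , drop = FALSE]
    top <- tab$gene[seq_len(floor(nrow(tab) * top_fraction))]
    kept <- intersect(top, promoter_peak_genes)
    if (length(kept) >= min_markers) markers[[ty]] <- kept
  }
  if (!length(markers))
    stop("all cell types filtered out of the signature")
  all_markers <- sort(unique(unlist(markers)))
  sig <- profiles[all_markers, names(markers), drop = FALSE]
  structure(list(signature = as.matrix(sig), markers = markers,
                 dropped = setdiff(names(de_tables), names(markers))),
            class = "signature")
}

#' Estimate mixture proportions by constrained least squares
#'
#' Nonnegative least squares of the bulk profile on the signature columns,
#' renormalized to the unit simplex. (This deliberately replaces any
#' published deconvolution engine's internals: the analysis-defined content
#' is the signature, not the solver.)
#'
#' @param signature a `signature` object or a markers x types matrix.
#' @param bulk named numeric bulk profile covering all signature markers.
#' @return named proportions, nonnegative, summing to 1.
#' @export
deconvolve <- function(signature, bulk) {
  sig <- if (inherits(signature, "signature")) signature$signature
    else as.matrix(signature)
  if (!is.null(names(bulk))) {
    if (!all(rownames(sig) %in% names(bulk)))
      stop("bulk profile does not cover all signature markers")
    bulk <- bulk[rownames(sig)]
  }
  stopifnot(length(bulk) == nrow(sig))
  if (qr(sig)$rank < ncol(sig))
    warning("rank-deficient signature; minimum-norm solution returned")
  x <- pracma::lsqnonneg(sig, as.numeric(bulk))$x
  if (sum(x) == 0) stop("degenerate fit: all-zero mixture")
  p <- x / sum(x)
  names(p) <- colnames(sig)
  p
}
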