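#' Concordance index (C-statistic)
#'
#' The probability, over unordered pairs of observations, that predicted
#' and observed values are concordantly ordered; pairs tied in either
#' variable contribute 0.5. Equals 1 for perfectly concordant orderings,
#' 0 for perfectly discordant ones, and 0.5 when the observed values carry
#' no ordering at all.
#'
#' @param predicted,observed numeric vectors of equal length (>= 2).
#' @return C in `[0, 1]`.
#' @export
concordance_index <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2)
  dp <- sign(outer(predicted, predicted, "-"))
  do <- sign(outer(observed, observed, "-"))
  s <- dp * do
  up <- upper.tri(s)
  score <- ifelse(s[up] > 0, 1, ifelse(s[up] < 0, 0, 0.5))
  mean(score)
}

#' Per-gene best-fit methylation-expression model
#'
#' For each candidate region category (promoter, CpG island, exon,
#' intron, ...), a univariate linear regression of expression log2
#' fold-change on the category's methylation hyper value is fitted across
#' genes and its Pearson correlation recorded. Each gene is then assigned
#' the category explaining it best: among categories with a negative
#' genome-wide correlation, the one minimizing the gene's absolute
#' standardized residual; genes with no negative-correlation category fall
#' back to the globally most negative one. Model fit is summarised by the
#' concordance index of the combined per-gene predictions.
#'
#' @param hyper_mat numeric matrix, genes x categories, of region
#'   methylation hyper values (rownames = gene ids).
#' @param expr_lfc numeric vector of expression log2 fold-changes, aligned
#'   to rows of `hyper_mat`.
#' @return object of class `best_fit`: list with `categories` (per-category
#'   r, slope, intercept, residual sd), `genes` (selected category,
#'   prediction, observation), `C` (concordance index) and
#'   `fit_correlation` (Pearson r of prediction vs observation).
#' @export
best_fit_expression_model <- function(hyper_mat, expr_lfc) {
  hyper_mat <- as.matrix(hyper_mat)
  stopifnot(ncol(hyper_mat) >= 2, nrow(hyper_mat) >= 10,
            nrow(hyper_mat) == length(expr_lfc))
  if (is.null(rownames(hyper_mat)))
    rownames(hyper_mat) <- paste0("gene", seq_len(nrow(hyper_mat)))
  cats <- colnames(hyper_mat)
  fits <- lapply(cats, function(k) {
    x <- hyper_mat[, k]
    use <- !is.na(x) & !is.na(expr_lfc)
    if (sum(use) < 3 || stats::sd(x[use]) == 0) return(NULL)
    fit <- stats::lm(expr_lfc[use] ~ x[use])
    sigma <- stats::sd(stats::residuals(fit))
    list(r = stats::cor(x[use], expr_lfc[use]),
         intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         sigma = if (sigma > 0) sigma else 1)
  })
  names(fits) <- cats
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) stop("no usable category column")
  fits <- fits[keep]
  cat_tab <- data.frame(category = names(fits),
                        r = vapply(fits, `[[`, numeric(1), "r"),
                        slope = vapply(fits, `[[`, numeric(1), "slope"),
                        intercept = vapply(fits, `[[`, numeric(1),
                                           "intercept"),
                        sigma = vapply(fits, `[[`, numeric(1), "sigma"),
                        row.names = NULL)
  negative <- cat_tab$category[cat_tab$r < 0]
  fallback <- cat_tab$category[which.min(cat_tab$r)]
  n <- nrow(hyper_mat)
  sel <- character(n); pred <- numeric(n)
  for (i in seq_len(n)) {
    cand <- negative[!is.na(hyper_mat[i, negative])]
    if (!length(cand)) {
      cand <- fallback
      if (is.na(hyper_mat[i, fallback])) {
        sel[i] <- NA_character_; pred[i] <- NA_real_
        next
      }
    }
    zres <- vapply(cand, function(k) {
      f <- fits[[k]]
      abs(expr_lfc[i] - (f$intercept + f$slope * hyper_mat[i, k])) /
        f$sigma
    }, numeric(1))
    sel[i] <- cand[which.min(zres)]
    f <- fits[[sel[i]]]
    pred[i] <- f$intercept + f$slope * hyper_mat[i, sel[i]]
  }
  use <- !is.na(pred) & !is.na(expr_lfc)
  genes <- data.frame(gene_id = rownames(hyper_mat),
                      selected_category = sel,
                      predicted = pred,
                      observed = expr_lfc,
                      row.names = NULL)
  structure(list(categories = cat_tab,
                 genes = genes,
                 C = concordance_index(pred[use], expr_lfc[use]),
                 fit_correlation = stats::cor(pred[use], expr_lfc[use])),
            class = "best_fit")
}

#' @export
print.best_fit <- function(x, ...) {
  cat("best_fit over", nrow(x$genes), "genes; overall C =",
      round(x$C, 3), "\n")
  tab <- table(x$genes$selected_category)
  for (k in names(tab)) cat("  ", k, ":", tab[[k]], "genes\n")
  invisible(x)
}

#' Gene-by-category methylation hyper matrix
#'
#' Convenience wrapper assembling the input of
#' [best_fit_expression_model()]: pooled methylation per compartment per
#' gene region category, turned into hyper log-ratios.
#'
#' @param track a `meth_track` with the two compartments in `pair`.
#' @param catalog region catalog (see [annotate_gene_regions()]).
#' @param categories category names to evaluate.
#' @param beta pseudocount for [hyper()].
#' @param pair compartment names, numerator first.
#' @return numeric matrix genes x categories.
#' @export
region_hyper_matrix <- function(track, catalog,
                                categories = c("promoter", "cpg_island",
                                               "exon", "intron"),
                                beta = 0.001, pair = c("GLOM", "TI")) {
  genes <- sort(unique(catalog$gene_id[!is.na(catalog$gene_id)]))
  out <- matrix(NA_real_, length(genes), length(categories),
                dimnames = list(genes, categories))
  for (g in genes) {
    for (k in categories) {
      rows <- catalog[!is.na(catalog$gene_id) & catalog$gene_id == g &
                        catalog$category == k, , drop = FALSE]
      if (!nrow(rows)) next
      pool <- function(cp) {
        cs <- 0; ts <- 0
        m <- track$compartments[[cp]]
        for (i in seq_len(nrow(rows))) {
          idx <- sites_in_region(track, rows[i, ])
          cs <- cs + sum(m$numC[idx, , drop = FALSE])
          ts <- ts + sum(m$numT[idx, , drop = FALSE])
        }
        if (cs + ts == 0) NA_real_ else cs / (cs + ts)
      }
      a <- pool(pair[1]); b <- pool(pair[2])
      if (!is.na(a) && !is.na(b)) out[g, k] <- hyper(a, b, beta = beta)
    }
  }
  out
}
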