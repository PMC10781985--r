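#' Gene model container
#'
#' Bundles a gene table and an exon table. The TSS is the first transcribed
#' base: `start` for plus-strand genes, `end - 1` for minus-strand genes.
#'
#' @param genes data.frame with columns `gene_id`, `symbol`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open span). A `tss` column is
#'   derived if absent.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   exons of one gene must be disjoint, sorted, and inside the gene span.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  if (!"tss" %in% names(genes))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tss <- as.integer(genes$tss)
  validate_intervals(genes)
  validate_intervals(exons)
  bad_tss <- genes$tss != ifelse(genes$strand == "+", genes$start,
                                 genes$end - 1L)
  if (any(bad_tss))
    stop("tss must equal span start (+) or span end - 1 (-): ",
         paste(genes$gene_id[bad_tss], collapse = ", "))
  for (g in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    span <- genes[genes$gene_id == g, , drop = FALSE]
    if (nrow(span) != 1) stop("exon references unknown gene: ", g)
    if (any(ex$start < span$start) || any(ex$end > span$end))
      stop("exons of ", g, " extend beyond gene span")
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("exons of ", g, " overlap")
  }
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Promoters as fixed-width windows centered on the TSS
#'
#' A promoter is a `width` window centered on the transcription start site
#' (default 2 kb), clipped at the chromosome origin. Centering is
#' strand-independent.
#'
#' @param genes a `gene_models` object or a gene table with `tss`.
#' @param width even positive window width in bp.
#' @return interval table with a `gene_id` column; every promoter contains
#'   the TSS base.
#' @export
make_promoters <- function(genes, width = 2000L) {
  if (inherits(genes, "gene_models")) genes <- genes$genes
  stopifnot(width > 0, width %% 2 == 0)
  half <- as.integer(width / 2)
  intervals(chrom = genes$chrom,
            start = pmax(0L, genes$tss - half),
            end = genes$tss + half,
            gene_id = genes$gene_id)
}

#' Strand-aware 1-5 kb upstream blocks
#' @noRd
upstream_blocks <- function(genes, from_bp = 1000L, to_bp = 5000L) {
  if (inherits(genes, "gene_models")) genes <- genes$genes
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - to_bp, genes$tss + from_bp + 1L)
  end <- ifelse(plus, genes$tss - from_bp, genes$tss + to_bp + 1L)
  keep <- pmax(0L, start) < end
  intervals(chrom = genes$chrom[keep],
            start = pmax(0L, start[keep]),
            end = end[keep],
            gene_id = genes$gene_id[keep])
}

#' Build the per-gene region taxonomy
#'
#' Produces the annotatr-style catalog every summarisation step works over:
#' per gene the whole gene, promoter (2 kb centered on the TSS), the 1-5 kb
#' upstream block (strand-aware), exons and introns, plus the CpG taxonomy
#' (islands; shores flanking islands by `shore_bp`; shelves flanking shores
#' by `shelf_bp`; `cpg_inter` as the genomic complement, unowned).
#'
#' @param gm a `gene_models` object.
#' @param cpg_islands interval table of CpG islands; may carry `gene_id`
#'   for ownership (else assigned to the nearest-overlapping gene extended
#'   span, or left unowned).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param shore_bp,shelf_bp flank widths in bp.
#' @param promoter_width promoter window width in bp.
#' @param utrs optional interval table with `gene_id` and `category`
#'   (`"utr5"` / `"utr3"`), appended when the input annotation provides
#'   UTR features.
#' @return data.frame catalog: `chrom`, `start`, `end`, `gene_id`,
#'   `category`.
#' @export
annotate_gene_regions <- function(gm, cpg_islands = NULL, chrom_lengths,
                                  shore_bp = 2000L, shelf_bp = 2000L,
                                  promoter_width = 2000L, utrs = NULL) {
  stopifnot(inherits(gm, "gene_models"), !is.null(names(chrom_lengths)))
  genes <- gm$genes
  parts <- list()
  parts$whole_gene <- intervals(genes$chrom, genes$start, genes$end,
                                gene_id = genes$gene_id)
  prom <- make_promoters(gm, width = promoter_width)
  parts$promoter <- prom
  parts$upstream_1to5kb <- upstream_blocks(gm)
  parts$exon <- intervals(gm$exons$chrom, gm$exons$start, gm$exons$end,
                          gene_id = gm$exons$gene_id)
  if (!is.null(utrs) && nrow(utrs)) {
    stopifnot(all(c("gene_id", "category") %in% names(utrs)),
              all(utrs$category %in% c("utr5", "utr3")))
    for (u in unique(utrs$category)) {
      sel <- utrs[utrs$category == u, , drop = FALSE]
      parts[[u]] <- intervals(sel$chrom, sel$start, sel$end,
                              gene_id = sel$gene_id)
    }
  }
  introns <- lapply(unique(gm$exons$gene_id), function(g) {
    ex <- gm$exons[gm$exons$gene_id == g, , drop = FALSE]
    if (nrow(ex) < 2) return(NULL)
    data.frame(chrom = ex$chrom[-1], start = ex$end[-nrow(ex)],
               end = ex$start[-1], gene_id = g, stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, introns)
  if (!is.null(introns) && nrow(introns))
    parts$intron <- validate_intervals(introns)
  if (!is.null(cpg_islands) && nrow(cpg_islands)) {
    isl <- cpg_islands
    if (!"gene_id" %in% names(isl)) {
      ext <- intervals(genes$chrom, pmax(0L, genes$start - 5000L),
                       genes$end + 5000L, gene_id = genes$gene_id)
      hit <- overlap_intervals(isl, ext)
      isl$gene_id <- NA_character_
      first <- !duplicated(hit$index_a)
      isl$gene_id[hit$index_a[first]] <- ext$gene_id[hit$index_b[first]]
    }
    parts$cpg_island <- intervals(isl$chrom, isl$start, isl$end,
                                  gene_id = isl$gene_id)
    shores <- flank_both(isl, shore_bp)
    shores <- carve(shores, isl)
    if (nrow(shores)) parts$cpg_shore <- shores
    shelves <- flank_both(rbind_flanks(isl, shore_bp), shelf_bp)
    shelves <- carve(shelves, rbind(isl[c("chrom", "start", "end")],
                                    shores[c("chrom", "start", "end")]))
    if (nrow(shelves)) parts$cpg_shelf <- shelves
    covered <- rbind(isl[c("chrom", "start", "end")],
                     shores[c("chrom", "start", "end")],
                     shelves[c("chrom", "start", "end")])
  } else {
    covered <- data.frame(chrom = character(), start = integer(),
                          end = integer())
  }
  genome <- intervals(names(chrom_lengths), 0L,
                      as.integer(chrom_lengths))
  inter <- setdiff_intervals(genome, covered)
  if (nrow(inter)) {
    inter$gene_id <- NA_character_
    parts$cpg_inter <- inter
  }
  parts <- parts[vapply(parts, nrow, 1L) > 0]
  out <- do.call(rbind, lapply(names(parts), function(cat) {
    p <- parts[[cat]]
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               gene_id = if ("gene_id" %in% names(p)) p$gene_id else
                 NA_character_,
               category = cat, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# flanking blocks on each side of every interval, clipped at 0
flank_both <- function(df, width) {
  left <- data.frame(chrom = df$chrom, start = pmax(0L, df$start - width),
                     end = df$start,
                     gene_id = df$gene_id %||% NA_character_)
  right <- data.frame(chrom = df$chrom, start = df$end,
                      end = df$end + width,
                      gene_id = df$gene_id %||% NA_character_)
  out <- rbind(left, right)
  out[out$start < out$end, , drop = FALSE]
}

# widen intervals by `width` on both sides (support for shelf construction)
rbind_flanks <- function(df, width) {
  data.frame(chrom = df$chrom, start = pmax(0L, df$start - width),
             end = df$end + width,
             gene_id = df$gene_id %||% NA_character_)
}

# remove the bases of `cut` from `df`, keeping gene ownership per piece
carve <- function(df, cut) {
  if (!nrow(df)) return(df)
  gid <- if ("gene_id" %in% names(df)) df$gene_id else
    rep(NA_character_, nrow(df))
  if (!nrow(cut)) {
    out <- df[, c("chrom", "start", "end")]
    out$gene_id <- gid
    rownames(out) <- NULL
    return(out)
  }
  res <- GenomicRanges::subtract(
    as_granges(df),
    GenomicRanges::reduce(as_granges(cut), ignore.strand = TRUE),
    ignore.strand = TRUE)
  n_per <- S4Vectors::elementNROWS(res)
  gr <- unlist(res, use.names = FALSE)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    gene_id = rep(gid, n_per),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Catalog entries used as a gene's agreement/Gisch units
#'
#' The units are the gene's promoter, upstream block, exons and introns,
#' position-sorted; these are the rows the AUC filter and the agreement
#' coding operate on.
#' @param catalog output of [annotate_gene_regions()].
#' @param gene_id single gene identifier.
#' @return interval table with `category`, sorted by (start, end, category).
#' @export
gene_region_units <- function(catalog, gene_id) {
  u <- catalog[!is.na(catalog$gene_id) & catalog$gene_id == gene_id &
                 catalog$category %in%
                   c("promoter", "upstream_1to5kb", "exon", "intron"), ,
               drop = FALSE]
  u <- u[order(u$start, u$end, u$category), , drop = FALSE]
  rownames(u) <- NULL
  u
}
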