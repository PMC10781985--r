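#' Read a BED file (BED3+ subset)
#'
#' Native 0-based half-open coordinates; name/score/strand read when
#' present. Lines are sorted on read.
#' @param path file path.
#' @return interval table.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  df <- data.frame(chrom = as.character(dt[[1]]),
                   start = as.integer(dt[[2]]),
                   end = as.integer(dt[[3]]), stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) df$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) df$score <- as.numeric(dt[[5]])
  if (ncol(dt) >= 6) df$strand <- as.character(dt[[6]])
  if (nrow(df) && any(df$end <= df$start))
    stop("non-positive interval width in ", path,
         " (is the file 1-based inclusive?)")
  sort_intervals(df)
}

#' Write an interval table as BED
#' @param df interval table; `name`, `score`, `strand` written if present.
#' @param path output path.
#' @param header optional comment lines (leading `#`).
#' @export
write_bed <- function(df, path, header = NULL) {
  cols <- c("chrom", "start", "end")
  for (c4 in c("name", "score", "strand"))
    if (c4 %in% names(df)) cols <- c(cols, c4) else break
  writeLines(if (is.null(header)) character() else paste0("# ", header),
             path)
  if (nrow(df))
    data.table::fwrite(df[, cols, drop = FALSE], path, sep = "\t",
                       col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Uses `gene` and `exon` features; GTF's 1-based inclusive coordinates
#' are converted to the package's 0-based half-open convention on read.
#' @param path GTF path.
#' @return a [gene_models()] object.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  gene_rows <- md$type == "gene"
  exon_rows <- md$type == "exon"
  genes <- data.frame(gene_id = md$gene_id[gene_rows],
                      symbol = md$gene_id[gene_rows],
                      chrom = as.character(md$seqnames[gene_rows]),
                      strand = as.character(md$strand[gene_rows]),
                      start = md$start[gene_rows] - 1L,
                      end = md$end[gene_rows])
  exons <- data.frame(gene_id = md$gene_id[exon_rows],
                      chrom = as.character(md$seqnames[exon_rows]),
                      start = md$start[exon_rows] - 1L,
                      end = md$end[exon_rows])
  gene_models(genes, exons)
}

#' Write gene models as GTF
#' @param gm a `gene_models` object.
#' @param path output path.
#' @export
write_gtf_genes <- function(gm, path) {
  row <- function(chrom, feat, start, end, strand, gid)
    paste(chrom, "epikidney", feat, start + 1L, end, ".", strand, ".",
          sprintf('gene_id "%s";', gid), sep = "\t")
  g <- gm$genes
  lines <- row(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id)
  e <- merge(gm$exons, g[, c("gene_id", "strand")], by = "gene_id")
  e <- e[order(e$gene_id, e$start), ]
  lines <- c(lines, row(e$chrom, "exon", e$start, e$end, e$strand,
                        e$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-CpG bisulfite count table
#'
#' Long TSV with columns `chrom`, `pos`, `numC`, `numT`, `sample`,
#' `compartment`; reshaped into a [meth_track()]. Every (sample,
#' compartment) must cover the identical site list.
#' @param path TSV path.
#' @return a `meth_track`.
#' @export
read_cpg_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "pos", "numC", "numT", "sample", "compartment")
  if (!all(need %in% names(dt)))
    stop("CpG table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  sites <- unique(data.frame(chrom = dt$chrom, pos = dt$pos))
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$pos)
  comps <- list()
  for (cp in sort(unique(dt$compartment))) {
    sub <- dt[dt$compartment == cp, ]
    samples <- sort(unique(sub$sample))
    numC <- matrix(NA_integer_, nrow(sites), length(samples),
                   dimnames = list(NULL, samples))
    numT <- numC
    for (s in samples) {
      ss <- sub[sub$sample == s, ]
      m <- match(paste(ss$chrom, ss$pos), key)
      if (anyNA(m) || nrow(ss) != nrow(sites))
        stop("sample ", s, "/", cp, " does not cover the full site list")
      numC[m, s] <- ss$numC
      numT[m, s] <- ss$numT
    }
    comps[[cp]] <- list(numC = numC, numT = numT)
  }
  meth_track(sites, comps)
}

#' Write a `meth_track` as a long TSV
#' @param track a `meth_track`.
#' @param path output path.
#' @export
write_cpg_table <- function(track, path) {
  rows <- list()
  for (cp in names(track$compartments)) {
    m <- track$compartments[[cp]]
    for (s in colnames(m$numC)) {
      rows[[paste(cp, s)]] <- data.frame(chrom = track$sites$chrom,
                                         pos = track$sites$pos,
                                         numC = m$numC[, s],
                                         numT = m$numT[, s],
                                         sample = s, compartment = cp)
    }
  }
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' Read a sparse cell matrix from MatrixMarket + sidecar TSVs
#'
#' @param mtx_path MatrixMarket file (features x cells).
#' @param features_path one feature id per line (optionally more columns).
#' @param barcodes_path one cell barcode per line.
#' @return sparse matrix with dimnames; errors on any dimension mismatch.
#' @export
read_cell_matrix <- function(mtx_path, features_path, barcodes_path) {
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  # binary matrices round-trip through MatrixMarket "pattern" files
  if (methods::is(m, "nMatrix") || methods::is(m, "lMatrix"))
    m <- methods::as(m, "dMatrix")
  feats <- data.table::fread(features_path, header = FALSE, sep = "\t")
  bcs <- data.table::fread(barcodes_path, header = FALSE, sep = "\t")
  if (nrow(feats) != nrow(m))
    stop("feature file ", features_path, " has ", nrow(feats),
         " rows but matrix has ", nrow(m))
  if (nrow(bcs) != ncol(m))
    stop("barcode file ", barcodes_path, " has ", nrow(bcs),
         " rows but matrix has ", ncol(m))
  dimnames(m) <- list(as.character(feats[[1]]), as.character(bcs[[1]]))
  m
}

#' Write the full synthetic dataset to disk
#'
#' Emits the same plain-text formats the pipeline reads: CpG TSV, BED peak
#' sets, bedGraph coverage tracks (run-length compressed), a GTF, MTX cell
#' matrices with sidecars, label/expression TSVs, and the planted truth as
#' JSON.
#' @param ds a `sim_dataset`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_cpg_table(ds$meth, p("cpg_counts.tsv"))
  write_gtf_genes(ds$genome$models, p("genes.gtf"))
  write_bed(ds$genome$cpg_islands, p("cpg_islands.bed"))
  for (m in names(ds$marks$peaks))
    write_bed(ds$marks$peaks[[m]], p(paste0("peaks_", m, ".bed")))
  for (m in names(ds$marks$tracks)) {
    tr <- ds$marks$tracks[[m]]
    rows <- do.call(rbind, lapply(names(tr$values), function(ch) {
      r <- tr$values[[ch]]
      ends <- cumsum(S4Vectors::runLength(r))
      data.frame(chrom = ch, start = c(0L, ends[-length(ends)]),
                 end = ends, value = S4Vectors::runValue(r))
    }))
    write_bedgraph(rows[rows$value != 0, ], p(paste0("track_", m,
                                                     ".bedgraph")))
  }
  Matrix::writeMM(ds$cells$peaks_mat, p("peaks.mtx"))
  Matrix::writeMM(ds$cells$genes_mat, p("genes.mtx"))
  writeLines(rownames(ds$cells$peaks_mat), p("peaks_features.tsv"))
  writeLines(rownames(ds$cells$genes_mat), p("genes_features.tsv"))
  bc <- sprintf("cell%04d", seq_along(ds$cells$labels))
  writeLines(bc, p("barcodes.tsv"))
  data.table::fwrite(data.frame(barcode = bc, label = ds$cells$labels),
                     p("labels.tsv"), sep = "\t")
  data.table::fwrite(ds$cells$peak_coords, p("peak_coords.tsv"),
                     sep = "\t")
  data.table::fwrite(ds$expression$expression, p("expression_lfc.tsv"),
                     sep = "\t")
  data.table::fwrite(data.frame(gene = names(ds$cells$bulk),
                                value = ds$cells$bulk),
                     p("bulk_profile.tsv"), sep = "\t")
  truth <- ds$truth
  truth$chrom_lengths <- as.list(ds$genome$chrom_lengths)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' Read a dataset directory back into memory
#'
#' Loads the formats [write_dataset()] emits (CpG TSV, GTF, BED peak
#' sets, bedGraph tracks, MTX cell matrices with sidecars, labels and
#' expression TSVs, truth JSON) and validates cross-file consistency:
#' coordinate sanity is checked by every reader, matrix dimensions are
#' checked against their sidecars, and chromosome names of the peak sets
#' must appear in the truth's chromosome lengths.
#'
#' @param dir directory written by [write_dataset()].
#' @return list with `models`, `cpg_islands`, `chrom_lengths`, `meth`,
#'   `peaks`, `tracks`, `cells` (matrices + labels + coords),
#'   `expression`, `truth`.
#' @export
read_inputs <- function(dir) {
  p <- function(...) file.path(dir, ...)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  chrom_lengths <- unlist(truth$chrom_lengths)
  models <- read_gtf_genes(p("genes.gtf"))
  meth <- read_cpg_table(p("cpg_counts.tsv"))
  marks <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3", "ATAC")
  peaks <- lapply(marks, function(m) read_bed(p(paste0("peaks_", m,
                                                       ".bed"))))
  names(peaks) <- marks
  for (m in marks)
    if (nrow(peaks[[m]]) &&
        !all(peaks[[m]]$chrom %in% names(chrom_lengths)))
      stop("peak set ", m, " names chromosomes absent from truth.json")
  tracks <- lapply(marks, function(m)
    signal_track(read_bedgraph(p(paste0("track_", m, ".bedgraph"))),
                 chrom_lengths, mark = m))
  names(tracks) <- marks
  peaks_mat <- read_cell_matrix(p("peaks.mtx"), p("peaks_features.tsv"),
                                p("barcodes.tsv"))
  genes_mat <- read_cell_matrix(p("genes.mtx"), p("genes_features.tsv"),
                                p("barcodes.tsv"))
  labels <- data.table::fread(p("labels.tsv"), sep = "\t")
  if (!identical(labels$barcode, colnames(peaks_mat)))
    stop("labels.tsv barcodes do not match the matrix barcodes")
  list(models = models,
       cpg_islands = read_bed(p("cpg_islands.bed")),
       chrom_lengths = chrom_lengths,
       meth = meth, peaks = peaks, tracks = tracks,
       cells = list(peaks_mat = peaks_mat, genes_mat = genes_mat,
                    labels = labels$label,
                    peak_coords = as.data.frame(
                      data.table::fread(p("peak_coords.tsv")))),
       expression = as.data.frame(
         data.table::fread(p("expression_lfc.tsv"))),
       truth = truth)
}

#' Pipeline configuration
#'
#' Bundles every analysis threshold with its published default: hyper
#' pseudocount 0.001; dips at methylation <= 0.4 over >= 50 bp; CpG
#' coverage > 5 reads in all samples; Bonferroni alpha 0.05 for the
#' single-cell tests; 2% expressed/accessible-cell floors; 0.25 fold-change
#' filter where requested; 2 kb promoters; 5 kb TSS windows; 1 kb genome
#' bins.
#'
#' @param seed integer seed for the synthetic dataset.
#' @param outdir output directory for [run_pipeline()].
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param beta,dip_max_ml,dip_min_len_bp,min_coverage,alpha,min_pct,
#'   new_peak_threshold,min_abs_log2fc,promoter_width,tss_window_bp,bin_bp,
#'   dip_window_bp,correction analysis thresholds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("epikidney_"),
                            sim = sim_config(seed = seed),
                            beta = 0.001, dip_max_ml = 0.4,
                            dip_min_len_bp = 50L, min_coverage = 5L,
                            alpha = 0.05, min_pct = 0.02,
                            new_peak_threshold = 0.02,
                            min_abs_log2fc = 0.25,
                            promoter_width = 2000L,
                            tss_window_bp = 5000L, bin_bp = 1000L,
                            dip_window_bp = 10L,
                            correction = "BH") {
  sim$seed <- as.integer(seed)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[sort(names(cfg))], auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on the synthetic dataset
#'
#' Stages run in dependency order: region annotation, methylation
#' summaries and compartment tests, dip calling, per-gene AUC filters and
#' chromatin states, cross-technology agreement (kappa, Fisher),
#' single-cell DE/DA/new peaks and gene open-chromatin AUC, the best-fit
#' methylation-expression model, and signature deconvolution. Every output
#' table carries a header with the config hash and seed; a JSON report of
#' per-stage counts is written alongside.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages?
#' @return list of stage results, invisibly; outputs under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config[setdiff(names(config), "outdir")])
  meta <- paste0("config_hash=", hash, " seed=", config$seed)
  say <- function(...) if (!quiet) message("[epikidney] ", ...)
  out_tsv <- function(df, name) {
    path <- file.path(config$outdir, name)
    writeLines(paste0("# ", meta), path)
    suppressWarnings(data.table::fwrite(df, path, sep = "\t",
                                        append = TRUE, col.names = TRUE))
    path
  }
  res <- list(config = config)

  say("simulate: seed ", config$seed)
  ds <- simulate_dataset(config$sim)
  res$dataset <- ds

  say("methylation: coverage filter and region summaries")
  meth <- filter_cpgs(ds$meth, config$min_coverage)
  cat_rows <- ds$catalog[!is.na(ds$catalog$gene_id) &
                           ds$catalog$category %in%
                             c("whole_gene", "promoter", "exon", "intron",
                               "cpg_island"), , drop = FALSE]
  rm_tab <- region_methylation(meth, cat_rows, beta = config$beta,
                               correction = config$correction)
  res$region_methylation <- rm_tab
  out_tsv(rm_tab, "region_methylation.tsv")

  say("dips: TI windows of ", config$dip_window_bp, " bp")
  windows <- windowed_methylation(meth, "TI", config$dip_window_bp)
  dips <- call_methyl_dips(windows, config$dip_max_ml,
                           config$dip_min_len_bp)
  res$dips <- dips
  write_bed(dips, file.path(config$outdir, "dips.bed"), header = meta)

  say("states: ", nrow(ds$marks$peaks$ATAC), " ATAC anchors")
  promoters <- make_promoters(ds$genome$models, config$promoter_width)
  gene_bodies <- ds$genome$models$genes
  anchors <- unique(rbind(
    ds$marks$peaks$ATAC[, c("chrom", "start", "end")],
    ds$marks$peaks$H3K27me3[, c("chrom", "start", "end")]))
  states <- annotate_states(sort_intervals(anchors), ds$marks$peaks,
                            promoters, gene_bodies, dips = dips)
  res$states <- states
  out_tsv(states, "chromatin_states.tsv")

  say("upset and dip filtering")
  res$upset <- upset_counts(ds$marks$peaks$ATAC,
                            c(ds$marks$peaks[c("H3K27ac", "H3K4me1",
                                               "H3K4me3", "H3K27me3")],
                              list(dip = dips)))
  out_tsv(res$upset, "upset_counts.tsv")
  res$atac_with_dips <- filter_peaks_by_dips(ds$marks$peaks$ATAC, dips)

  say("agreement: per-gene kappa and genome-wide Fisher")
  dnam_track <- methylation_signal_track(meth, "TI",
                                         ds$genome$chrom_lengths,
                                         config$dip_window_bp)
  kap <- list()
  for (g in ds$genome$models$genes$gene_id) {
    units <- gene_region_units(ds$catalog, g)
    if (nrow(units) < 2) next
    gene <- ds$genome$models$genes[
      ds$genome$models$genes$gene_id == g, ]
    calls <- list(
      ATAC = gisch_filter(ds$marks$tracks$ATAC, gene, units, "peak"),
      H3K4me3 = gisch_filter(ds$marks$tracks$H3K4me3, gene, units,
                             "peak"),
      WGBS = gisch_filter(dnam_track, gene, units, "dip"))
    coding <- code_gene_regions(calls)
    ka <- kappa_between(coding, "ATAC", "H3K4me3")
    kw <- kappa_between(coding, "ATAC", "WGBS")
    kap[[g]] <- data.frame(gene_id = g, kappa_atac_k4me3 = ka$kappa,
                           kappa_atac_wgbs = kw$kappa,
                           n_units = ka$n_units)
  }
  kap <- do.call(rbind, kap)
  rownames(kap) <- NULL
  res$kappa <- kap
  res$kappa_summary <- kappa_summary(kap$kappa_atac_k4me3)
  out_tsv(kap, "kappa.tsv")
  bins <- genome_bins(ds$genome$chrom_lengths, config$bin_bp)
  res$fisher <- fisher_association(
    overlaps_any(bins, ds$marks$peaks$ATAC),
    overlaps_any(bins, dips))

  say("cell states: DE, DA, new peaks, gene AUC")
  cells <- ds$cells
  res$de <- de_genes_wilcoxon(cells$genes_mat, cells$labels, "adaptive",
                              "reference", alpha = config$alpha,
                              min_pct = config$min_pct)
  out_tsv(res$de, "de_genes.tsv")
  da <- da_peaks_lr(cells$peaks_mat, cells$labels, "adaptive",
                    "reference", alpha = config$alpha,
                    peaks = cells$peak_coords)
  da <- find_new_peaks(da, config$new_peak_threshold)
  res$da <- da
  out_tsv(as.data.frame(da), "da_peaks.tsv")
  pb <- pseudobulk(cells$peaks_mat, cells$labels)
  res$gene_auc <- do.call(rbind, lapply(
    seq_len(nrow(ds$genome$models$genes)), function(i) {
      g <- ds$genome$models$genes[i, ]
      auc <- gene_open_chromatin_auc(pb$fractions, cells$peak_coords, g,
                                     config$tss_window_bp)
      cbind(data.frame(gene_id = g$gene_id), as.data.frame(t(auc)))
    }))
  out_tsv(res$gene_auc, "gene_open_chromatin_auc.tsv")

  say("signature deconvolution")
  res$deconv <- tryCatch({
    de_tables <- lapply(c("reference", "adaptive", "other"), function(t) {
      others <- setdiff(unique(cells$labels), t)
      lab2 <- ifelse(cells$labels == t, t, "rest")
      de_genes_wilcoxon(cells$genes_mat, lab2, t, "rest",
                        alpha = config$alpha, min_pct = config$min_pct)
    })
    names(de_tables) <- c("reference", "adaptive", "other")
    expr_pb <- pseudobulk(cells$genes_mat, cells$labels)
    profiles <- t(t(expr_pb$sums) /
                    as.numeric(table(cells$labels)[colnames(expr_pb$sums)]))
    sig <- build_signature(de_tables, cells$promoter_peak_genes,
                           profiles)
    list(signature = sig,
         proportions = deconvolve(sig, cells$bulk[
           rownames(sig$signature)]))
  }, error = function(e) {
    say("deconvolution skipped: ", conditionMessage(e))
    NULL
  })

  say("best-fit methylation-expression model")
  bf <- best_fit_expression_model(ds$expression$hyper,
                                  ds$expression$expression$log2fc)
  res$best_fit <- bf
  out_tsv(bf$genes, "best_fit_genes.tsv")

  report <- list(
    config_hash = hash, seed = config$seed,
    n_cpg_sites = nrow(meth$sites),
    n_regions_tested = nrow(rm_tab),
    n_dips = nrow(dips),
    n_planted_dips = nrow(ds$truth$planted_dips),
    n_state_calls = nrow(states),
    n_de_genes = sum(res$de$is_de),
    n_da_peaks = sum(da$is_da),
    n_new_peaks = sum(da$is_new_peak),
    G_T = res$kappa_summary$G_T,
    fisher_p = res$fisher$p_value,
    overall_C = bf$C)
  if (!is.null(res$deconv))
    report$mixture_estimate <- as.list(res$deconv$proportions)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  res$report <- report
  say("done: ", config$outdir)
  invisible(res)
}

#' Methylation as a signal track (for AUC filters)
#'
#' Pooled window methylation of one compartment written onto a per-base
#' track; windows without CpG coverage are 0.
#' @param track a `meth_track`.
#' @param compartment compartment name.
#' @param chrom_lengths named integer vector.
#' @param window_bp pooling window.
#' @return a `signal_track` with mark `"DNAm"`.
#' @export
methylation_signal_track <- function(track, compartment, chrom_lengths,
                                     window_bp = 10L) {
  w <- windowed_methylation(track, compartment, window_bp)
  w <- w[!is.na(w$ml), , drop = FALSE]
  w$value <- w$ml
  signal_track(w[, c("chrom", "start", "end", "value")], chrom_lengths,
               mark = "DNAm")
}
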