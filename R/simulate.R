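#' Configuration of the synthetic multi-modal dataset
#'
#' The defaults define the miniature study conditions every stage is
#' exercised under: 2 chromosomes of 1 Mb, 50 genes, 4 bisulfite samples
#' per compartment, 3 cell types of 300 cells, a planted mixture of
#' (0.6, 0.3, 0.1), 20 planted injury genes, and methylation levels of
#' 0.85 (background) vs 0.10 (dips).
#'
#' @param seed integer seed; every generator derives its stream from it
#'   with a fixed per-stage offset.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes total genes (split evenly over chromosomes).
#' @param n_samples bisulfite samples per compartment.
#' @param high_ml,low_ml background and dip methylation levels.
#' @param coverage_mean mean per-CpG read coverage (Poisson).
#' @param frac_active,frac_repressed promoter state probabilities (the
#'   remainder is background).
#' @param enhancers_per_chrom planted intergenic enhancers per chromosome.
#' @param p_k4me1_at_promoter probability an active promoter also carries
#'   H3K4me1 (the mark is free at promoters).
#' @param peak_height,track_noise_lambda rectangular peak signal height
#'   and Poisson noise-floor rate per 50 bp for coverage tracks.
#' @param n_cells_per_type cells per cell type
#'   (reference / adaptive / other).
#' @param n_marker_genes_per_type type-specific marker genes in the
#'   expression panel (0 disables the marker blocks).
#' @param marker_log2fc,n_injury_genes,injury_log2fc,n_null_genes
#'   expression panel structure; injury genes are differential between
#'   adaptive and reference cells with alternating sign.
#' @param dropout per-count dropout probability on expression counts.
#' @param peak_base_rate,da_up_rate,da_down_rate,new_peak_rate,other_rate
#'   per-cell accessibility rates for null, differential and new peaks.
#' @param n_da_up,n_da_down,n_new_adaptive,n_new_reference planted peak
#'   class counts.
#' @param mixture named cell-type proportions of the synthetic bulk.
#' @param bulk_noise_frac relative Gaussian noise on the bulk profile.
#' @param expr_slope,expr_noise_frac expression model: log2FC =
#'   -slope x hyper(causal region) + Gaussian noise with
#'   sd = expr_noise_frac x sd(signal).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 1e6L,
                       n_genes = 50L, n_samples = 4L,
                       high_ml = 0.85, low_ml = 0.10,
                       coverage_mean = 30,
                       frac_active = 0.4, frac_repressed = 0.2,
                       enhancers_per_chrom = 5L,
                       p_k4me1_at_promoter = 0.5,
                       peak_height = 5, track_noise_lambda = 0.2,
                       n_cells_per_type = 300L,
                       n_marker_genes_per_type = 200L,
                       marker_log2fc = 1.5,
                       n_injury_genes = 20L, injury_log2fc = 1,
                       n_null_genes = 40L,
                       dropout = 0.2,
                       peak_base_rate = 0.4,
                       da_up_rate = 0.6, da_down_rate = 0.15,
                       new_peak_rate = 0.5, other_rate = 0.3,
                       n_da_up = 5L, n_da_down = 5L,
                       n_new_adaptive = 3L, n_new_reference = 2L,
                       mixture = c(reference = 0.6, adaptive = 0.3,
                                   other = 0.1),
                       bulk_noise_frac = 0.05,
                       expr_slope = 1, expr_noise_frac = 0.25) {
  stopifnot(0 <= low_ml, low_ml < high_ml, high_ml <= 1,
            abs(sum(mixture) - 1) < 1e-8)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# seeds per generator stage, all < 2^31
stage_seed <- function(cfg, stage) {
  offsets <- c(genome = 101L, methylation = 202L, marks = 303L,
               cells = 404L, expression = 505L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

# map a TSS-relative half-open interval to absolute coordinates,
# mirrored on the minus strand
rel2abs <- function(tss, strand, rel_start, rel_end) {
  if (strand == "+") c(tss + rel_start, tss + rel_end)
  else c(tss - rel_end + 1L, tss - rel_start + 1L)
}

#' Generate the synthetic genome and its planted truth
#'
#' Places non-overlapping genes (2-5 exons each) in evenly spaced slots,
#' assigns every promoter a chromatin state, plants intergenic enhancer
#' loci, a CpG island upstream of every gene, low-methylation dip zones at
#' active promoters and enhancers, and one causal region category
#' (promoter / CpG island / exon / intron) with a compartment methylation
#' difference per gene.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_genome`: `config`, `models`
#'   (a [gene_models()]), `cpg_islands`, `enhancers`, `chrom_lengths`, and
#'   `truth` (`region_states`, `planted_dips`, `causal`, `mixture`).
#' @export
simulate_genome <- function(cfg = sim_config()) {
  set.seed(stage_seed(cfg, "genome"))
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  slot <- floor(cfg$chrom_length / per_chrom)
  if (slot < 26000)
    stop("infeasible packing: need >= 26 kb per gene slot, got ", slot)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_lengths <- stats::setNames(rep(as.integer(cfg$chrom_length),
                                       cfg$n_chroms), chroms)
  genes <- list(); exons <- list(); islands <- list()
  states <- list(); dips <- list(); causal <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    n_here <- min(per_chrom, cfg$n_genes - (ci - 1L) * per_chrom)
    for (si in seq_len(n_here)) {
      gi <- gi + 1L
      gid <- sprintf("gene%03d", gi)
      strand <- sample(c("+", "-"), 1)
      slot_start <- (si - 1L) * slot
      # leave 6 kb of upstream room on either side of the slot
      tss <- as.integer(slot_start + 6000L +
                          ifelse(strand == "+", 0L, 9000L))
      len <- as.integer(sample(5000:9000, 1))
      # fixed proximal layout; distal blocks randomized
      n_ex <- sample(2:5, 1)
      rel_ex <- list(c(0L, 400L))
      cursor <- 2400L          # intron1 = [400, 2400)
      remaining <- len - cursor
      blocks <- 2L * (n_ex - 1L) - 1L   # exon2..exonN alternating
      widths <- stick_break(remaining, blocks, min_w = 300L)
      for (b in seq_len(blocks)) {
        if (b %% 2 == 1)      # odd blocks are exons
          rel_ex[[length(rel_ex) + 1]] <- c(cursor, cursor + widths[b])
        cursor <- cursor + widths[b]
      }
      span <- rel2abs(tss, strand, 0L, len)
      genes[[gi]] <- data.frame(gene_id = gid, symbol = gid,
                                chrom = chroms[ci], strand = strand,
                                start = span[1], end = span[2])
      exons[[gi]] <- do.call(rbind, lapply(rel_ex, function(re) {
        ab <- rel2abs(tss, strand, re[1], re[2])
        data.frame(gene_id = gid, chrom = chroms[ci],
                   start = ab[1], end = ab[2])
      }))
      isl <- rel2abs(tss, strand, -3200L, -2800L)
      islands[[gi]] <- data.frame(chrom = chroms[ci], start = isl[1],
                                  end = isl[2], gene_id = gid)
      state <- sample(c("active_promoter", "repressed", "background"), 1,
                      prob = c(cfg$frac_active, cfg$frac_repressed,
                               1 - cfg$frac_active - cfg$frac_repressed))
      prom <- c(tss - 1000L, tss + 1000L)
      states[[length(states) + 1]] <- data.frame(chrom = chroms[ci],
        start = prom[1], end = prom[2], name = gid, state = state)
      if (state == "active_promoter")
        dips[[length(dips) + 1]] <- data.frame(chrom = chroms[ci],
          start = tss - 150L, end = tss + 150L)
      # causal differential zone: covers the category's bases outside the
      # promoter window, so no category leaks into another. Promoters of
      # constitutively open (active) genes sit in a dip and have no
      # differential headroom, so they are not eligible as causal.
      cand <- c("promoter", "cpg_island", "exon", "intron")
      if (state == "active_promoter") cand <- setdiff(cand, "promoter")
      zone_cat <- sample(cand, 1)
      zone_rel <- switch(zone_cat,
        promoter = list(c(-1000L, 0L)),
        cpg_island = list(c(-3200L, -2800L)),
        exon = rel_ex[-1],                       # exon1 is in the promoter
        intron = {
          gaps <- list(c(1200L, 2400L))          # intron1 past the promoter
          for (j in seq_along(rel_ex)[-(1:2)])
            gaps[[length(gaps) + 1]] <- c(rel_ex[[j - 1]][2],
                                          rel_ex[[j]][1])
          gaps
        })
      delta <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.7)
      causal[[gi]] <- do.call(rbind, lapply(zone_rel, function(zr) {
        zab <- rel2abs(tss, strand, zr[1], zr[2])
        data.frame(gene_id = gid, category = zone_cat, delta = delta,
                   chrom = chroms[ci], start = zab[1], end = zab[2])
      }))
    }
    # intergenic enhancers, one per randomly chosen slot, far from any gene
    if (cfg$enhancers_per_chrom > per_chrom)
      stop("more enhancers than gene slots per chromosome")
    enh_slots <- sample(per_chrom, cfg$enhancers_per_chrom)
    for (ei in seq_len(cfg$enhancers_per_chrom)) {
      es <- as.integer((enh_slots[ei] - 1L) * slot + slot - 3000L)
      states[[length(states) + 1]] <- data.frame(chrom = chroms[ci],
        start = es, end = es + 400L,
        name = sprintf("enh_%s_%02d", chroms[ci], ei),
        state = "predicted_enhancer")
      dips[[length(dips) + 1]] <- data.frame(chrom = chroms[ci],
                                             start = es, end = es + 400L)
    }
  }
  models <- gene_models(do.call(rbind, genes), do.call(rbind, exons))
  truth <- list(region_states = do.call(rbind, states),
                planted_dips = sort_intervals(do.call(rbind, dips)),
                causal = do.call(rbind, causal),
                mixture = cfg$mixture)
  rownames(truth$region_states) <- rownames(truth$causal) <- NULL
  structure(list(config = cfg, models = models,
                 cpg_islands = do.call(rbind, islands),
                 chrom_lengths = chrom_lengths,
                 truth = truth),
            class = "sim_genome")
}

# split `total` into `k` integer widths >= min_w
stick_break <- function(total, k, min_w = 300L) {
  if (k == 1) return(total)
  if (total < k * min_w) stop("gene too short for its exon count")
  free <- total - k * min_w
  cuts <- sort(sample(0:free, k - 1, replace = TRUE))
  extra <- diff(c(0L, cuts, free))
  as.integer(min_w + extra)
}

#' Simulate per-CpG bisulfite counts for both compartments
#'
#' CpG sites are placed densely (8 bp) inside CpG islands and planted dip
#' zones, at 25 bp steps across gene neighborhoods, and sparsely (300 bp)
#' elsewhere. Per site, sample and compartment, coverage is Poisson and
#' the methylated count binomial around the regional level: `high_ml`
#' background, a compartment-split level inside each gene's causal zone
#' (GLOM = 0.65 + delta/4, TI = 0.65 - delta/4, keeping both compartments
#' above the dip ceiling), and `low_ml` in both compartments inside
#' planted dips (dips override causal zones).
#'
#' @param genome a `sim_genome`.
#' @param cfg optional config override (defaults to `genome$config`).
#' @return a [meth_track()] with compartments `GLOM` and `TI`.
#' @export
simulate_methylation <- function(genome, cfg = genome$config) {
  force(genome); force(cfg)   # evaluate promises before seeding
  set.seed(stage_seed(cfg, "methylation"))
  gn <- genome$models$genes
  sites <- list()
  for (ch in names(genome$chrom_lengths)) {
    pos <- seq(0L, genome$chrom_lengths[[ch]] - 1L, by = 300L)
    g <- gn[gn$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      lo <- max(0L, min(g$start[i], g$tss[i] - 5500L) - 200L)
      hi <- min(genome$chrom_lengths[[ch]],
                max(g$end[i], g$tss[i] + 5500L) + 200L)
      pos <- c(pos, seq(lo, hi - 1L, by = 25L))
    }
    dense <- rbind(genome$cpg_islands[genome$cpg_islands$chrom == ch,
                                      c("chrom", "start", "end")],
                   genome$truth$planted_dips[
                     genome$truth$planted_dips$chrom == ch, ,
                     drop = FALSE])
    for (i in seq_len(nrow(dense)))
      pos <- c(pos, seq(dense$start[i], dense$end[i] - 1L, by = 8L))
    sites[[ch]] <- data.frame(chrom = ch, pos = sort(unique(pos)))
  }
  sites <- do.call(rbind, sites)
  n <- nrow(sites)
  ml_glom <- rep(cfg$high_ml, n)
  ml_ti <- rep(cfg$high_ml, n)
  cz <- genome$truth$causal
  for (i in seq_len(nrow(cz))) {
    in_z <- sites$chrom == cz$chrom[i] & sites$pos >= cz$start[i] &
      sites$pos < cz$end[i]
    # centered at 0.65 with quarter-delta split so neither compartment
    # crosses the 0.4 dip ceiling (causal zones are differential, not dips)
    ml_glom[in_z] <- min(max(0.65 + cz$delta[i] / 4, 0.02), 0.98)
    ml_ti[in_z] <- min(max(0.65 - cz$delta[i] / 4, 0.02), 0.98)
  }
  pd <- genome$truth$planted_dips
  for (i in seq_len(nrow(pd))) {
    in_d <- sites$chrom == pd$chrom[i] & sites$pos >= pd$start[i] &
      sites$pos < pd$end[i]
    ml_glom[in_d] <- cfg$low_ml
    ml_ti[in_d] <- cfg$low_ml
  }
  draw <- function(ml) {
    numC <- matrix(0L, n, cfg$n_samples)
    numT <- matrix(0L, n, cfg$n_samples)
    for (s in seq_len(cfg$n_samples)) {
      cov <- stats::rpois(n, cfg$coverage_mean)
      c_s <- stats::rbinom(n, cov, ml)
      numC[, s] <- c_s
      numT[, s] <- cov - c_s
    }
    colnames(numC) <- colnames(numT) <- paste0("s", seq_len(cfg$n_samples))
    list(numC = numC, numT = numT)
  }
  meth_track(sites, list(GLOM = draw(ml_glom), TI = draw(ml_ti)))
}

#' Simulate histone mark and ATAC peak sets and coverage tracks
#'
#' Peak sets follow the planted states: active promoters get
#' H3K4me3 + H3K27ac + ATAC (H3K4me1 with probability
#' `p_k4me1_at_promoter`), enhancers get H3K4me1 + H3K27ac + ATAC without
#' H3K4me3, repressed promoters get H3K27me3, background gets nothing.
#' Coverage tracks are rectangular peak signal of height `peak_height`
#' over a Poisson noise floor drawn per 50 bp bin
#' (`track_noise_lambda = 0` gives noiseless tracks).
#'
#' @inheritParams simulate_methylation
#' @return list: `peaks` (named list of interval tables per mark) and
#'   `tracks` (named list of [signal_track()]s).
#' @export
simulate_mark_tracks <- function(genome, cfg = genome$config) {
  force(genome); force(cfg)   # evaluate promises before seeding
  set.seed(stage_seed(cfg, "marks"))
  rs <- genome$truth$region_states
  marks <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3", "ATAC")
  peaks <- stats::setNames(vector("list", length(marks)), marks)
  add <- function(mark, chrom, start, end, name) {
    peaks[[mark]][[length(peaks[[mark]]) + 1]] <<-
      data.frame(chrom = chrom, start = start, end = end, name = name)
  }
  for (i in seq_len(nrow(rs))) {
    ctr <- (rs$start[i] + rs$end[i]) %/% 2
    ch <- rs$chrom[i]; nm <- rs$name[i]
    if (rs$state[i] == "active_promoter") {
      add("H3K4me3", ch, ctr - 500L, ctr + 500L, nm)
      add("H3K27ac", ch, ctr - 500L, ctr + 500L, nm)
      add("ATAC", ch, ctr - 350L, ctr + 350L, nm)
      if (stats::runif(1) < cfg$p_k4me1_at_promoter)
        add("H3K4me1", ch, ctr - 500L, ctr + 500L, nm)
    } else if (rs$state[i] == "predicted_enhancer") {
      add("H3K4me1", ch, rs$start[i], rs$end[i], nm)
      add("H3K27ac", ch, rs$start[i], rs$end[i], nm)
      add("ATAC", ch, rs$start[i], rs$end[i], nm)
    } else if (rs$state[i] == "repressed") {
      add("H3K27me3", ch, ctr - 500L, ctr + 500L, nm)
    }
  }
  peaks <- lapply(peaks, function(p) {
    if (is.null(p)) return(data.frame(chrom = character(),
                                      start = integer(), end = integer(),
                                      name = character()))
    sort_intervals(do.call(rbind, p))
  })
  tracks <- lapply(marks, function(m) {
    vals <- lapply(names(genome$chrom_lengths), function(ch) {
      L <- genome$chrom_lengths[[ch]]
      nbin <- ceiling(L / 50)
      noise <- if (cfg$track_noise_lambda > 0)
        stats::rpois(nbin, cfg$track_noise_lambda) else rep(0, nbin)
      v <- rep(noise, each = 50)[seq_len(L)]
      pk <- peaks[[m]]
      pk <- pk[pk$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(pk)))
        v[(pk$start[i] + 1):pk$end[i]] <-
          v[(pk$start[i] + 1):pk$end[i]] + cfg$peak_height
      S4Vectors::Rle(v)
    })
    names(vals) <- names(genome$chrom_lengths)
    structure(list(values = vals, chrom_lengths = genome$chrom_lengths,
                   mark = m), class = "signal_track")
  })
  names(tracks) <- marks
  list(peaks = peaks, tracks = tracks)
}

#' Simulate single-nucleus peak and gene matrices with planted truth
#'
#' Cell types are `reference`, `adaptive` and `other`. Accessibility is
#' Bernoulli per cell on binarized peaks with per-class rates: planted DA
#' peaks are shifted up in one type, planted new peaks have rate 0 in the
#' comparator type, all else is at the base rate. The expression panel
#' holds type-marker blocks (for the signature/deconvolution arm), injury
#' genes differential between adaptive and reference (alternating sign),
#' and null genes; dropout is applied to expression counts. A synthetic
#' bulk profile mixing the type expression profiles at the planted
#' proportions (plus relative Gaussian noise) is included.
#'
#' @param genome a `sim_genome`.
#' @param marks output of [simulate_mark_tracks()] (supplies ATAC peaks).
#' @param cfg optional config override.
#' @return list of class `sim_cells`: `peaks_mat`, `genes_mat` (sparse,
#'   features x cells), `labels`, `peak_coords`, `bulk`, and truth fields
#'   `da_truth`, `new_peak_truth`, `de_truth`, `marker_truth`,
#'   `promoter_peak_genes`, `mixture`.
#' @export
simulate_cells <- function(genome, marks, cfg = genome$config) {
  force(genome); force(marks); force(cfg)  # promises before seeding
  set.seed(stage_seed(cfg, "cells"))
  types <- c("reference", "adaptive", "other")
  n_cells <- cfg$n_cells_per_type
  labels <- rep(types, each = n_cells)
  pk <- marks$peaks$ATAC
  n_pk <- nrow(pk)
  need <- cfg$n_da_up + cfg$n_da_down + cfg$n_new_adaptive +
    cfg$n_new_reference
  if (n_pk < need)
    stop("not enough ATAC peaks (", n_pk, ") for the planted classes (",
         need, ")")
  pk$peak <- sprintf("peak%03d", seq_len(n_pk))
  cls <- rep("null", n_pk)
  idx <- sample(n_pk, need)
  cls[idx] <- rep(c("up_in_adaptive", "up_in_reference", "new_adaptive",
                    "new_reference"),
                  times = c(cfg$n_da_up, cfg$n_da_down,
                            cfg$n_new_adaptive, cfg$n_new_reference))
  rate <- matrix(cfg$peak_base_rate, n_pk, 3,
                 dimnames = list(pk$peak, types))
  rate[, "other"] <- cfg$other_rate
  rate[cls == "up_in_adaptive", "adaptive"] <- cfg$da_up_rate
  rate[cls == "up_in_adaptive", "reference"] <- cfg$da_down_rate
  rate[cls == "up_in_reference", "reference"] <- cfg$da_up_rate
  rate[cls == "up_in_reference", "adaptive"] <- cfg$da_down_rate
  rate[cls == "new_adaptive", "adaptive"] <- cfg$new_peak_rate
  rate[cls == "new_adaptive", "reference"] <- 0
  rate[cls == "new_reference", "reference"] <- cfg$new_peak_rate
  rate[cls == "new_reference", "adaptive"] <- 0
  peaks_mat <- do.call(cbind, lapply(types, function(t)
    matrix(stats::rbinom(n_pk * n_cells, 1, rep(rate[, t], n_cells)),
           n_pk, n_cells)))
  dimnames(peaks_mat) <- list(pk$peak, NULL)
  peaks_mat <- methods::as(Matrix::Matrix(peaks_mat, sparse = TRUE),
                           "CsparseMatrix")
  # expression panel
  n_mk <- cfg$n_marker_genes_per_type
  panel <- c(if (n_mk > 0) paste0("mk_", rep(types, each = n_mk), "_",
                                  sprintf("%03d", seq_len(n_mk))),
             if (cfg$n_injury_genes > 0)
               sprintf("injury_%03d", seq_len(cfg$n_injury_genes)),
             if (cfg$n_null_genes > 0)
               sprintf("null_%03d", seq_len(cfg$n_null_genes)))
  n_g <- length(panel)
  lambda <- matrix(stats::runif(n_g, 0.5, 3), n_g, 3,
                   dimnames = list(panel, types))
  marker_truth <- list()
  if (n_mk > 0) for (t in types) {
    rows <- paste0("mk_", t, "_", sprintf("%03d", seq_len(n_mk)))
    lambda[rows, t] <- lambda[rows, t] * 2^cfg$marker_log2fc
    marker_truth[[t]] <- rows
  }
  de_truth <- NULL
  if (cfg$n_injury_genes > 0) {
    rows <- sprintf("injury_%03d", seq_len(cfg$n_injury_genes))
    sgn <- rep(c(1, -1), length.out = cfg$n_injury_genes)
    # total-preserving effects: pair every up-gene with a down-gene whose
    # baseline compensates it exactly (lambda_down = lambda_up * 2^lfc),
    # so non-injury genes stay exchangeable between the two cell states
    # after per-cell normalization (no compositional artifact)
    n_pair <- ceiling(cfg$n_injury_genes / 2)
    u <- stats::runif(n_pair, 0.5, 1.5)
    base <- as.numeric(rbind(u, u * 2^cfg$injury_log2fc))
    base <- base[seq_len(cfg$n_injury_genes)]
    lambda[rows, ] <- base
    lambda[rows, "adaptive"] <- base * 2^(sgn * cfg$injury_log2fc)
    de_truth <- data.frame(gene = rows,
                           log2fc_true = sgn * cfg$injury_log2fc)
  }
  # library-size matching across types (exact for the paired injury
  # design; absorbs the residual imbalance of the marker blocks)
  lambda <- sweep(lambda, 2, colSums(lambda) / mean(colSums(lambda)),
                  "/")
  genes_mat <- do.call(cbind, lapply(types, function(t)
    matrix(stats::rpois(n_g * n_cells, rep(lambda[, t], n_cells)),
           n_g, n_cells)))
  if (cfg$dropout > 0)
    genes_mat <- genes_mat *
      matrix(stats::rbinom(length(genes_mat), 1, 1 - cfg$dropout),
             nrow(genes_mat))
  dimnames(genes_mat) <- list(panel, NULL)
  genes_mat <- methods::as(Matrix::Matrix(genes_mat, sparse = TRUE),
                           "CsparseMatrix")
  promoter_peak_genes <- panel[stats::runif(n_g) < 0.5 |
                                 grepl("^mk_", panel)]
  bulk <- as.numeric(lambda %*% cfg$mixture[types])
  bulk <- pmax(0, bulk * (1 + stats::rnorm(n_g, 0,
                                           cfg$bulk_noise_frac)))
  names(bulk) <- panel
  structure(list(peaks_mat = peaks_mat, genes_mat = genes_mat,
                 labels = labels,
                 peak_coords = pk[, c("chrom", "start", "end", "peak")],
                 da_truth = data.frame(peak = pk$peak, class = cls),
                 new_peak_truth = stats::setNames(
                   ifelse(cls == "new_adaptive", "adaptive",
                          ifelse(cls == "new_reference", "reference",
                                 NA_character_)), pk$peak),
                 de_truth = de_truth,
                 marker_truth = marker_truth,
                 promoter_peak_genes = promoter_peak_genes,
                 bulk = bulk,
                 expected_profiles = lambda,
                 mixture = cfg$mixture),
            class = "sim_cells")
}

#' Simulate compartment expression anti-correlated with causal methylation
#'
#' Per gene, the expression log2 fold-change between compartments is
#' `-expr_slope` times the measured hyper value of the gene's planted
#' causal region category, plus Gaussian noise with standard deviation
#' `expr_noise_frac` times the standard deviation of the noiseless signal.
#'
#' @param genome a `sim_genome`.
#' @param meth the [simulate_methylation()] track.
#' @param catalog optional pre-computed region catalog.
#' @param cfg optional config override.
#' @return list: `expression` (data.frame `gene_id`, `log2fc`),
#'   `hyper` (gene x category matrix), `causal` (planted categories).
#' @export
simulate_expression <- function(genome, meth, catalog = NULL,
                                cfg = genome$config) {
  force(genome); force(meth); force(catalog); force(cfg)
  set.seed(stage_seed(cfg, "expression"))
  if (is.null(catalog))
    catalog <- annotate_gene_regions(genome$models, genome$cpg_islands,
                                     genome$chrom_lengths)
  h <- region_hyper_matrix(meth, catalog)
  cz <- unique(genome$truth$causal[, c("gene_id", "category", "delta")])
  cz <- cz[order(cz$gene_id), , drop = FALSE]
  rownames(cz) <- NULL
  stopifnot(all(cz$gene_id %in% rownames(h)), !anyDuplicated(cz$gene_id))
  signal <- vapply(seq_len(nrow(cz)), function(i)
    h[cz$gene_id[i], cz$category[i]], numeric(1))
  if (anyNA(signal)) stop("causal region with undefined methylation")
  noise_sd <- cfg$expr_noise_frac * stats::sd(cfg$expr_slope * signal)
  lfc <- -cfg$expr_slope * signal + stats::rnorm(nrow(cz), 0, noise_sd)
  list(expression = data.frame(gene_id = cz$gene_id, log2fc = lfc),
       hyper = h, causal = cz)
}

#' Generate the complete synthetic multi-modal dataset
#'
#' Runs every generator in sequence under the config's seed and bundles
#' the results with the accumulated planted truth.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset`: `config`, `genome`, `catalog`,
#'   `meth`, `marks`, `cells`, `expression`, `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  genome <- simulate_genome(cfg)
  catalog <- annotate_gene_regions(genome$models, genome$cpg_islands,
                                   genome$chrom_lengths)
  meth <- simulate_methylation(genome, cfg)
  marks <- simulate_mark_tracks(genome, cfg)
  cells <- simulate_cells(genome, marks, cfg)
  expression <- simulate_expression(genome, meth, catalog, cfg)
  truth <- genome$truth
  truth$da_truth <- cells$da_truth
  truth$new_peak_truth <- cells$new_peak_truth
  truth$de_truth <- cells$de_truth
  truth$marker_truth <- cells$marker_truth
  structure(list(config = cfg, genome = genome, catalog = catalog,
                 meth = meth, marks = marks, cells = cells,
                 expression = expression, truth = truth),
            class = "sim_dataset")
}
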