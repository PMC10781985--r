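#!/usr/bin/env Rscript
# Cross-technology agreement: per gene, code the region units (promoter,
# upstream block, exons, introns) as peak / absent-peak with the per-gene
# AUC filter for ATAC and H3K4me3, and dip / absent-dip for TI
# methylation; quantify agreement with Cohen's kappa (mean across genes,
# G_T) and genome-wide association with a two-sided Fisher test on 1 kb
# bins.

suppressPackageStartupMessages(library(epikidney))

ds <- simulate_dataset(sim_config(seed = 1L))
dir.create("results", showWarnings = FALSE)

meth <- filter_cpgs(ds$meth)
dips <- call_methyl_dips(windowed_methylation(meth, "TI"))
dnam <- methylation_signal_track(meth, "TI", ds$genome$chrom_lengths)

rows <- list()
for (g in ds$genome$models$genes$gene_id) {
  units <- gene_region_units(ds$catalog, g)
  if (nrow(units) < 2) next
  gene <- ds$genome$models$genes[ds$genome$models$genes$gene_id == g, ]
  coding <- code_gene_regions(list(
    ATAC = gisch_filter(ds$marks$tracks$ATAC, gene, units, "peak"),
    H3K4me3 = gisch_filter(ds$marks$tracks$H3K4me3, gene, units, "peak"),
    WGBS = gisch_filter(dnam, gene, units, "dip")))
  rows[[g]] <- data.frame(
    gene_id = g,
    kappa_atac_k4me3 = kappa_between(coding, "ATAC", "H3K4me3")$kappa,
    kappa_atac_wgbs = kappa_between(coding, "ATAC", "WGBS")$kappa,
    n_units = nrow(coding))
}
kap <- do.call(rbind, rows)
data.table::fwrite(kap, "results/kappa.tsv", sep = "\t")

s <- kappa_summary(kap$kappa_atac_k4me3)
cat("ATAC vs H3K4me3: G_T =", round(s$G_T, 3), "over", nrow(kap),
    "genes\n")
print(s$bands)
cat("ATAC vs WGBS dips: G_T =",
    round(kappa_summary(kap$kappa_atac_wgbs)$G_T, 3), "\n")

bins <- genome_bins(ds$genome$chrom_lengths, 1000L)
fis <- fisher_association(overlaps_any(bins, ds$marks$peaks$ATAC),
                          overlaps_any(bins, dips))
cat("Fisher (ATAC x dips, 1 kb bins): OR =",
    round(fis$odds_ratio, 1), ", p =", format(fis$p_value), "\n")
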