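#!/usr/bin/env Rscript
# Chromatin-state arm: annotate anchors (ATAC and H3K27me3 peaks) with the
# mark-combination rules (active promoter / predicted enhancer /
# repressed), tabulate mark-dip co-occurrence as upset counts, and filter
# ATAC peaks to those overlapping TI methylation dips.

suppressPackageStartupMessages(library(epikidney))

ds <- simulate_dataset(sim_config(seed = 1L))
dir.create("results", showWarnings = FALSE)

meth <- filter_cpgs(ds$meth)
dips <- call_methyl_dips(windowed_methylation(meth, "TI"))

promoters <- make_promoters(ds$genome$models)
anchors <- unique(rbind(ds$marks$peaks$ATAC[, c("chrom", "start", "end")],
                        ds$marks$peaks$H3K27me3[, c("chrom", "start",
                                                    "end")]))
states <- annotate_states(anchors, ds$marks$peaks, promoters,
                          ds$genome$models$genes, dips = dips)
data.table::fwrite(states, "results/chromatin_states.tsv", sep = "\t")
cat("state calls over", nrow(states), "anchors:\n")
print(table(states$state))

# accuracy against the planted region states
rs <- ds$truth$region_states
ann <- annotate_states(rs[, c("chrom", "start", "end")], ds$marks$peaks,
                       promoters, ds$genome$models$genes)
acc <- mean(ann$state == ifelse(rs$state == "background", "unclassified",
                                rs$state))
cat("planted-state accuracy:", acc, "\n")

up <- upset_counts(ds$marks$peaks$ATAC,
                   c(ds$marks$peaks[c("H3K27ac", "H3K4me1", "H3K4me3",
                                      "H3K27me3")],
                     list(dip = dips)))
data.table::fwrite(up, "results/upset_counts.tsv", sep = "\t")
cat("top peak/dip co-occurrence combinations:\n")
print(utils::head(up, 4))

kept <- filter_peaks_by_dips(ds$marks$peaks$ATAC, dips)
cat("ATAC peaks overlapping a TI dip:", nrow(kept), "of",
    nrow(ds$marks$peaks$ATAC), "\n")
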