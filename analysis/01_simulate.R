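#!/usr/bin/env Rscript
# Generate the synthetic multi-modal kidney dataset with planted truth and
# write it to results/data/ in the interchange formats the pipeline reads
# (CpG TSV, GTF, BED peak sets, bedGraph tracks, MTX cell matrices, truth
# JSON). Every later analysis step starts from the same seeded generator,
# so this script's outputs are for inspection and external reuse.

suppressPackageStartupMessages(library(epikidney))

seed <- 1L
cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg)

dir.create("results", showWarnings = FALSE)
write_dataset(ds, "results/data")

cat("Synthetic dataset (seed ", seed, "):\n", sep = "")
cat("  genes:              ", nrow(ds$genome$models$genes), "\n")
cat("  CpG sites:          ", nrow(ds$meth$sites), "\n")
cat("  planted dips:       ", nrow(ds$truth$planted_dips), "\n")
cat("  ATAC peaks:         ", nrow(ds$marks$peaks$ATAC), "\n")
cat("  cells:              ", length(ds$cells$labels), " (",
    paste(names(table(ds$cells$labels)), table(ds$cells$labels),
          sep = "=", collapse = ", "), ")\n", sep = "")
cat("  planted DA classes: ",
    paste(names(table(ds$truth$da_truth$class)),
          table(ds$truth$da_truth$class), sep = "=", collapse = ", "),
    "\n")
cat("written to results/data/\n")
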