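# epikidney

Integrative analysis of the kidney epigenome across modalities: whole-genome
bisulfite methylation from laser-microdissected glomerular (GLOM) and
tubulointerstitial (TI) compartments, CUT&RUN histone marks, bulk ATAC open
chromatin, and single-nucleus multiome matrices for reference vs adaptive
(injured) epithelial cell states. The package implements each analysis stage
as a tested function and ships a seeded synthetic multi-modal generator with
planted ground truth, so the whole workflow runs and is verifiable without
any external data.

## What it computes

- **Region-summative methylation.** Per region, counts are pooled over CpGs
  and samples before the ratio is taken:
  `ml = Σ #C / Σ(#C + #T)`, per compartment. Relative methylation is the
  *Hyper* statistic `Hyper = log2((ml_GLOM + β) / (ml_TI + β))` with
  `β = 0.001`; positive values mean GLOM-hypermethylated. Compartments are
  compared per region with a two-sided Welch t-test plus multiple-testing
  correction. CpG sites require coverage > 5 reads in every sample.
- **Methylation dips.** Maximal runs of windowed methylation ≤ 0.4 spanning
  ≥ 50 bp — the low-methylation valleys that mark active regulatory DNA.
- **Per-gene AUC filter ("Gisch filter").** A gene region is called a peak
  when its signal density exceeds the whole-gene average (strictly), a dip
  when below it — the technology-independent region coding used for
  cross-assay comparison.
- **Chromatin states.** Rule-based calls from mark combinations:
  H3K4me3⁺/H3K27ac⁺ in a promoter → active promoter;
  H3K4me1⁺/H3K27ac⁺/H3K4me3⁻ outside promoters → predicted enhancer;
  H3K27me3⁺ otherwise → repressed.
- **Cross-technology agreement.** Cohen's kappa over per-gene region codings
  (mean across genes, `G_T`) and two-sided Fisher's exact tests over genome
  bins.
- **Cell-state analysis.** Wilcoxon DE genes and logistic-regression
  likelihood-ratio DA peaks (Bonferroni p < 0.05, |log2FC| > 0) between
  adaptive and reference cells; *new peaks* are DA peaks whose comparator
  state has open chromatin in fewer than 2% of cells; gene-level
  open-chromatin AUC sums accessible-cell fractions over peaks within 5 kb
  of the TSS.
- **Signature deconvolution.** Marker signatures from the top 10% of each
  type's DEGs with promoter histone peaks (types retained with ≥ 20
  markers), mixed proportions estimated by nonnegative least squares on the
  simplex.
- **Best-fit methylation–expression model.** Per gene, the region category
  (promoter, CpG island, exon, intron) whose methylation best explains
  expression log2 fold-change, via pooled negative-correlation regressions
  and per-gene residual minimization; overall fit is the concordance index
  (C-statistic).

## Worked example

```r
library(epikidney)
res <- run_pipeline(pipeline_config(seed = 1, outdir = "results/run"))
res$report
```

prints (seed 1, default miniature conditions):

```
n_cpg_sites          35269
n_dips               34        # = number planted
n_de_genes           419
n_da_peaks           15        # 5 up + 5 down + 5 new planted
n_new_peaks          5
G_T                  0.512
overall_C            0.904
mixture_estimate     reference 0.593, adaptive 0.306, other 0.101
```

The planted mixture was (0.6, 0.3, 0.1); all five planted new peaks are
recovered; the dip caller returns exactly the 34 planted dips. The numbered
drivers under `analysis/` (`01_simulate.R` … `06_expression_model.R`) run
the same stages one arm at a time, narrate what they find, and write their
tables under `results/`.

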