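---
title: "Integrating the kidney epigenome: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating the kidney epigenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epikidney)
```

This vignette is the package's account of its science: the statistical
models and rules each stage implements, the tunable parameters and why
their defaults are what they are, what the synthetic generator does and
does not emulate, and the numerical and design choices made where the
procedure left room.

## The measurement model

The package works on two kidney compartments isolated by laser
microdissection — glomeruli (GLOM) and tubulointerstitium (TI) — assayed
with whole-genome bisulfite sequencing, plus histone-mark and open
chromatin data on bulk tissue and single-nucleus multiome matrices for
epithelial cell states. All coordinates are 0-based half-open (the BED
convention); GTF input is converted on read.

### Region-summative methylation and the Hyper statistic

Per CpG site, sample and compartment we hold methylated (`numC`) and
unmethylated (`numT`) read counts. A site is kept only with coverage
strictly greater than 5 reads in *every* sample of both compartments —
a deliberately strict filter that guarantees every retained site is
quantified everywhere, so regional summaries never mix sample subsets.

Regional methylation pools counts *before* dividing:

$$ml = \frac{\sum_{i,\,s} numC_{i,s}}{\sum_{i,\,s} (numC_{i,s} + numT_{i,s})}$$

over the CpGs $s$ of the region and the selected samples $i$. The
sum-then-divide form weights sites by coverage; a mean of per-site ratios
would up-weight poorly covered sites. A region with zero pooled coverage
is undefined (`NA`), never 0 — zero would fake full demethylation.

Relative compartment methylation is the Hyper log-ratio

$$Hyper = \log_2 \frac{ml_{GLOM} + \beta}{ml_{TI} + \beta},
\qquad \beta = 0.001,$$

positive when the glomerulus is the more methylated compartment. The
pseudocount only matters near fully unmethylated regions and keeps the
ratio finite. Differential testing uses a two-sided Welch t-test on the
per-sample regional levels; Welch because there is no reason to assume
equal variances between compartments. The default multiple-testing
correction is Benjamini–Hochberg for genome-wide region scans, with
Bonferroni selectable where a family-wise guarantee is wanted (the
single-cell tests below always use Bonferroni).

### Methylation dips

A dip is a maximal run of windowed pooled methylation at or below 0.4
extending at least 50 bp. Both constants are exposed
(`dip_max_ml`, `dip_min_len_bp`). Windowing is required because CpGs are
sparse at single-base resolution; the default window is 10 bp,
configurable. Windows with no CpG are undefined and terminate a run, so a
dip is never longer than its CpG support — a conservative choice that
avoids bridging unmeasured gaps. Dips are called on the TI compartment by
default (the tubulointerstitium dominates cortical tissue), selectable
per compartment.

### The per-gene AUC filter

To compare technologies with incommensurable signal scales, each gene's
region units (promoter, 1–5 kb upstream block, exons, introns) are coded
peak/absent per technology by comparing the unit's area under the signal
curve with the whole gene's. Two readings of "average AUC" are possible:
raw summed signal, or per-base density. The package compares densities by
default (`normalize = TRUE`): comparing a 200 bp exon's raw AUC against a
60 kb gene's raw AUC is scale-inconsistent, and density is the only
reading under which a uniform track yields the expected all-tie outcome.
Ties are never called — "greater than" is strict — so a zero-signal gene
produces no peaks and no dips. For methylation the comparison is
inverted (`mode = "dip"`): regulatory regions are methylation valleys.

### Chromatin states

States are a pure function of mark presence and location, applied in
order: H3K4me3⁺ and H3K27ac⁺ inside a promoter is an active promoter
(H3K4me1 free either way, the +/- of promoter biology); H3K4me1⁺ and
H3K27ac⁺ without H3K4me3 outside promoters is a predicted enhancer;
H3K27me3⁺ otherwise is repressed; anything else is unclassified. Mark
presence means at least one base of overlap with that mark's peak set —
peak calling itself is upstream of this package. The enhancer rule has a
strict variant additionally requiring the peak to be extragenic; the
permissive variant is the default because exonic and intronic enhancers
are biologically real and the strict reading is only needed when
enhancers must be unambiguous. Promoters are 2 kb windows centered on the
TSS, strand-independent.

### Agreement statistics

Per-gene codings from two technologies are compared with Cohen's kappa;
`G_T` is the unweighted mean kappa across genes, with counts per
agreement band. Genes whose two codings are both constant have chance
agreement 1 and an undefined kappa; the package takes the limit
convention — identical constants score 1, differing constants score −1 —
and flags the value as degenerate. Genome-wide co-occurrence of binary
features uses a two-sided Fisher exact test over fixed-width bins
(default 1 kb, a knob, since any binning is a resolution choice). The
odds ratio is reported with a Haldane 0.5 correction when a single cell
is empty, and as `Inf` for perfect association; the p-value always comes
from the uncorrected table.

### Cell-state differential analysis

Expression DE uses a two-sided Wilcoxon rank-sum test on log-normalized
counts (counts scaled to 10,000 per cell, then `log1p` — the conventional
preprocessing for rank-based single-cell tests), testing genes expressed
in more than 2% of either group's cells, Bonferroni-corrected, with an
optional |log2FC| > 0.25 filter. Accessibility DA binarizes peaks per
cell (count > 0 = "possessing open chromatin") and tests each peak by the
likelihood ratio of a logistic regression of group on accessibility
against the intercept-only null. With a single binary predictor that LR
statistic has the closed 2×2 G-test form, which is what the code
computes; a test verifies it against `glm()` deviances. No latent
covariates enter the null — the intercept-only comparison is the
documented choice. Fold changes use a pseudocount of 0.001 on both sides;
a DA peak needs Bonferroni p < 0.05 and |log2FC| > 0. A *new peak* is a
DA peak whose down-group has accessible chromatin in strictly fewer than
2% of its cells — chromatin newly opened in one state.

Gene-level open chromatin sums accessible-cell fractions over the peaks
fully contained in ±5 kb of the TSS; a peak overlapping the TSS base
itself always counts. Containment (rather than any-overlap) is the
stricter, reproducible reading of "within 5 kb".

### Signature deconvolution

Cell-type signatures take each type's marker DEGs (positive fold change,
ranked by effect), keep the top 10%, intersect with genes carrying a
promoter peak in H3K27ac, H3K4me1 or H3K4me3, and retain the type only
when at least 20 markers survive; confounded types can be dropped a
priori. Mixture proportions are estimated by nonnegative least squares of
the bulk profile on the signature columns, renormalized to the simplex.
The solver is deliberately plain constrained least squares: the
analysis-defined content is the signature construction, and any
well-behaved simplex regression recovers the mixture given it.

### The best-fit methylation–expression model

Two phrasings must be reconciled: category selection by "most negative
correlation" and model fit by "greatest C-statistic". The package does
both, in sequence: (1) per category, a univariate regression of
expression log2FC on the category's Hyper value across genes, recording
Pearson r; (2) per gene, the candidate set is the categories with
negative genome-wide r, and the gene takes the candidate minimizing its
absolute standardized residual (genes with no negative-r category fall
back to the most negative one); (3) overall fit is the concordance index
of the combined per-gene predictions — the probability that a random
gene pair is concordantly ordered, ties counting one half. The Pearson
correlation of predictions is also reported (`fit_correlation`) since
the C-statistic's exact definition in this setting admits both readings;
the concordance index is the default. Constant methylation columns are
excluded rather than fitted. Note that because category regressions are
pooled genome-wide, even noiseless data gives C slightly below 1 when
causal categories are mixed: off-category genes shift each regression's
intercept, which can swap prediction order *between* categories without
affecting recovery of the categories themselves.

## The synthetic data generator

Every stage is exercised on a generated miniature dataset with planted
truth. Defaults define the study conditions: 2 chromosomes × 1 Mb, 50
genes with 2–5 exons in fixed slots, 4 bisulfite samples per compartment
at ~30× CpG coverage, background methylation 0.85 against dips of 0.10,
three cell types (reference / adaptive / other) of 300 cells, 5 + 5
planted DA peaks (rates 0.6 vs 0.15), 3 + 2 planted new peaks (rate 0.5
vs exactly 0), 20 planted injury genes at |log2FC| = 1, 200 marker genes
per type for the signature arm, 20% expression dropout, and a planted
bulk mixture of (0.6, 0.3, 0.1) with 5% relative noise. Each generator
stage draws from its own stream (seed plus a fixed stage offset), so
stages are independently reproducible; a fixed seed gives byte-identical
outputs end to end.

Choices worth knowing about:

- **Every gene is multi-exonic (2–5 exons).** Each gene must be able to
  host exon and intron candidate regions for the expression model; the
  region taxonomy itself handles single-exon genes (tested separately).
- **Geometry keeps categories separable.** The causal differential zone
  of a gene covers its category's bases *outside* the 2 kb promoter
  window, so no category's signal leaks into another; CpG islands are
  planted upstream of the promoter for the same reason. Constitutively
  open (active) promoters sit inside a dip and have no differential
  headroom, so they are not eligible as causal promoters.
- **Dips and differential zones are disjoint regimes.** Planted dips are
  low in *both* compartments (0.10); causal zones split around 0.65
  (± delta/4, delta ∈ ±[0.3, 0.7]) so neither compartment crosses the 0.4
  dip ceiling. Differential methylation and dip calling therefore test
  different planted structure.
- **Expression is generated from measured methylation.** The expression
  log2FC of a gene is −slope × (its causal category's *measured* Hyper)
  plus Gaussian noise with sd = 0.25 × sd(signal), so the planted
  relation includes the binomial measurement noise a real experiment
  would carry.
- **Library-size-matched cell types.** Planted injury effects come in
  exactly compensating up/down pairs and type columns are rescaled to a
  common expected total, so after per-cell normalization non-planted
  genes are exchangeable between cell states. Without this, planted
  effects shift library sizes and rank tests correctly reject "null"
  genes for compositional reasons — a real artifact the generator must
  not bake in when recovery is scored against planted truth.
- **Accessibility is Bernoulli on binarized peaks,** not fragment
  counts: the DA and new-peak rules operate on per-cell accessibility
  indicators, so fragment-level simulation would add realism the tested
  rules never see.

What the generator does *not* emulate — and hence what passing tests do
not show about real tissue: read-level bisulfite conversion errors,
non-CpG methylation, fragment-level ATAC structure, doublets and ambient
RNA, batch effects, cell-type proportion shifts between donors, and
genuinely continuous (rather than rectangular) peak shapes. Recovery
results on synthetic data validate the implementations and their rules,
not the biology of any particular tissue.

## Numerical choices and degenerate inputs

- Zero-coverage regions are `NA` and excluded, never zero.
- The t-test returns t = 0, p = 1 for two constant equal groups and
  p = 0 for constant separated groups.
- Gisch ties (region density exactly the gene average) are absent calls.
- Empty cell types and unlabeled cells are errors, not silent drops.
- Peaks accessible in no cell and genes expressed in neither group are
  skipped, not tested (this also keeps Bonferroni denominators honest).
- The overlap engine sorts pairs (a-index, then b-index);
  adjacency under half-open coordinates is not overlap.
- Rank-deficient signatures warn and return the minimum-norm solution.

## Problem sizes in the test suite

The suite runs the full default conditions; the heavier recovery
analyses use 200 genes on 2 × 3 Mb chromosomes over 20 seeds (best-fit
recovery), 10 seeds of 300 + 300 cells (DE recovery), 10 × 2000 null
peaks (DA calibration) and 1000 null regions (t-test calibration) —
sizes chosen so each analysis has the statistical resolution its claim
needs while the whole suite completes in a few minutes on one CPU.

## Known limitations

- The Gisch filter's density comparison is one of two defensible
  readings of a whole-gene "average AUC"; the raw-sum variant is
  available via `normalize = FALSE`.
- Kappa's degenerate-gene convention (±1 for constant codings) is a
  documented choice; excluding such genes from `G_T` is the obvious
  alternative and can be done by filtering on the degenerate flag.
- The deconvolution solver assumes the bulk profile is (proportional to)
  a nonnegative mixture of the signature columns; strong platform
  effects between bulk and reference profiles are not modeled.
- Transcript isoforms, alternative promoters and UTR-specific analyses
  are out of scope; UTR categories appear only when provided by the
  input annotation.
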