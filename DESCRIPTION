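Package: epikidney
Title: Integrative Analysis of the Kidney Epigenome Across Modalities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates laser-microdissected whole-genome bisulfite
    methylation, CUT&RUN histone marks, bulk ATAC and single-nucleus
    multiome data from kidney compartments. Implements region-summative
    methylation with the Hyper log-ratio statistic, methylation dip
    calling, AUC-based per-gene peak/dip calling, rule-based chromatin
    state annotation, cross-technology agreement via Cohen's kappa and
    Fisher's exact test, adaptive-cell-state differential expression and
    accessibility with new-peak detection, marker-signature deconvolution,
    and a per-gene best-fit methylation-expression model. A seeded
    synthetic multi-modal generator with planted ground truth makes every
    stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    Matrix,
    data.table,
    jsonlite,
    pracma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
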