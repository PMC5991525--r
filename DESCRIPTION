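Package: teCorepress
Title: Repeat-Aware Co-Repression Analysis of Transposable Elements and Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing co-repression of transposable elements and
    nearby genes by heterochromatin corepressors (TRIM28, the HUSH complex and
    their cofactors). Implements family-level repeat derepression testing with
    a negative-binomial count model, derivation of co-repressed gene sets,
    repeat-proximity enrichment of gene sets against random gene backgrounds,
    ChIP peak reproducibility, clustering, histone-mark overlap and
    peak-to-repeat assignment statistics, LINE-1 evolutionary age and
    divergence classification, IP/input RPKM binding enrichment, and an
    upstream-LTR orientation-bias test. A synthetic-genome simulator with
    planted ground truth provides a fully reproducible test bed for every
    stage, and a pipeline driver runs the analysis end to end from a YAML
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, GeneRegulation, Transcriptomics, ChIPSeq, Software
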