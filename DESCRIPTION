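Package: fourCscreen
Title: 4C-Seq Viewpoint Interaction Quantification and Enhancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies circular chromosome conformation capture (4C-seq)
    viewpoint interaction profiles from fragment-level read assignments:
    in-silico restriction digestion, artifact-fragment filtering, fixed
    2 kb window counts normalized to reads per million (RPM), distance-decay
    background modelling with per-window significance calls, and
    replicate-intersected high-fidelity interaction sites. Compares
    profiles between conditions (1 Mb binned correlation, clustering, PCA,
    overlap sets) and performs negative-binomial differential interaction
    analysis with |log2 fold change| and adjusted p-value thresholds.
    Screens cis interaction regions against H3K27ac and ATAC-seq peaks for
    candidate active enhancers reduced to the maximum-accessibility window,
    annotates evolutionary conservation, and scans candidate sequences for
    E-boxes and position-weight-matrix motifs. A seeded synthetic-data
    generator plants enhancer contacts with known effect sizes so every
    stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    S4Vectors,
    optparse,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
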