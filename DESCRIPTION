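Package: enhancerscope
Title: Enhancer Prioritization and Deletion-Consequence Analysis for a
    Lymphoid Gene Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated workflow for prioritizing candidate enhancers at
    a gene locus and quantifying the consequences of CRISPR enhancer
    deletion. Combines reporter-assay (CapStarr-seq style) activity scoring,
    Hi-C chromatin-topology analysis (Knight-Ruiz matrix balancing,
    insulation scores, TAD boundary calling, virtual 4C), 4C-seq fragment
    profile smoothing and interaction calling, transcription-factor overlap
    integration, and delta-delta-Ct qPCR expression analysis. A synthetic
    locus generator produces every raw input with known ground truth so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    BiocGenerics,
    stats,
    utils,
    tools,
    methods,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
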