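Package: ifnsynergy
Title: Motif Classification, Kinetics and Synergy Analysis of Interferon-Induced STAT1 Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for the downstream analysis of interferon-stimulated
    transcription-factor binding and gene expression. Classifies STAT1
    ChIP-seq peaks by GAS and ISRE consensus motif content, identifies
    inducible peaks from normalized signal time courses and clusters their
    kinetics, links peaks to their closest expressed genes with a
    promoter/distal call, normalizes RNA-seq counts and calls
    interferon-stimulated genes, and quantifies synergy between GAF and
    ISGF3 with a per-gene Enhancement score compared across quartiles.
    Ships a synthetic-data generator that plants ground-truth motif
    categories, binding kinetics, dose gating and expression synergy so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    mclust,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    jsonlite
Config/testthat/edition: 3
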