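Package: chromattn
Title: Attention-Based Modeling of Histone Codes and 3D Chromatin
    Interactions for Gene Expression Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts gene expression from histone-modification ChIP-seq
    signals using a three-level attention architecture: a promoter
    self-attention encoder over multi-resolution binned signals in a 40 kbp
    window around the TSS, an encoder-decoder attention module that updates
    the promoter embedding against each distal putative cis-regulatory
    element (pCRE) in 3D chromatin contact with it, and a gated
    set-attention module that integrates the full interaction landscape
    with normalized promoter-capture Hi-C frequencies injected as an
    attention bias. Includes the full feature pipeline (signal binning,
    interaction filtering, chromosome-disjoint cross-validation), training
    with a decoupled weight-decay optimizer, attention-map extraction,
    predicted cis-regulatory impact (PCRI) scoring and clustering, and a
    self-contained synthetic-epigenome simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pROC,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
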