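Package: acetoscope
Title: Bioenergetics and Dual-Platform Transcriptomics of Acetogens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying acetogen physiology from transcriptome data.
    Implements a stoichiometric electron-carrier ledger model of acetogen
    bioenergetics (Wood-Ljungdahl pathway, Rnf and Nfn carrier exchange,
    urea-cycle and amino-acid degradation ATP yields with proton-gradient
    accounting), an RPKM-based differential-expression pipeline with
    cross-platform (microarray and RNA-Seq) reconciliation and ranking, a
    proteome amino-acid composition outlier screen, and seeded synthetic-data
    generators with ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
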