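Package: bclut
Title: Barcode-Fragment Look-Up Tables and Purity QC for Barcoded Plasmid Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment workflow for barcoded plasmid libraries sequenced
    with paired-end reads: extraction of degenerate (VHDB)x5 barcodes and
    genomic fragments by flank matching, seed-and-extend unique alignment to
    a reference, construction of a barcode-to-fragment look-up table with a
    per-barcode purity metric, and validation of barcode error-correction by
    sphere and message-passing clustering over the Levenshtein distance.
    Includes a ground-truthed synthetic-data stack: a dUTP/UDG fragmentation
    size model, a library constructor with unique degenerate barcodes, and a
    paired-read simulator with Poisson depth, singlet inflation, per-base
    errors and configurable template-switching chimera rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
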