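Package: skiptally
Title: Targeted Exon-Skipping Quantification in Single-Nuclei RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies exon-skipping transcripts in droplet
    single-nuclei RNA-seq libraries without alignment. Designs
    junction-spanning k-mers from a spliced transcript model, scans raw
    paired FASTQ for exact k-mer matches, collapses PCR duplicates via cell
    barcodes and UMIs, and reports per-cell-type skip frequencies. Includes
    exact small-sample Mann-Whitney tests for cell-type composition shifts,
    nuclei quality-control filtering of sparse count matrices, and a
    seeded 10x-style read simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    Biostrings,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
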