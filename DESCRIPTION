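Package: ibless
Title: Analysis Toolkit for i-BLESS Double-Strand Break Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational pipeline for single-nucleotide-resolution DNA
    double-strand break (DSB) mapping with i-BLESS: barcode-aware selection of
    break-proximal reads, strand-aware break-end profiling, windowed
    hypergeometric detection of fragile (DSB-rich) regions with k-mer
    mappability filtering, nucleosome-periodicity quality control via auto-
    and cross-correlation against MNase-seq coverage, intra- and inter-strand
    G-quadruplex motif scanning with loop-length fragility statistics,
    restriction/homing endonuclease cut-precision and off-target analysis,
    permutation-based feature enrichment, and a fully seeded synthetic-data
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
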