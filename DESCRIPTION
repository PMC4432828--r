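Package: bsmethr
Title: Bisulfite Methylation Analysis of Genomes and Repeat Amplicons with
    Synthetic Read Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bisulfite-sequencing methylation analysis driven by a
    synthetic bisulfite read generator, so every stage is verifiable against
    known truth. Covers conversion-efficiency estimation from an unmethylated
    spike-in, genome-scale cytosine-count and per-site methylation metrics with
    Fisher-test differential calling and gene annotation, and a repeat-amplicon
    pipeline (Alu/LINE-1 consensus amplicons): bisulfite-space primer location,
    semi-global alignment, per-read CpG/TpG dinucleotide frequencies,
    distribution-shift chi-square tests, CpG-TpG correlation, and one- versus
    two-component Gaussian mixture detection of bidirectional methylation
    change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
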