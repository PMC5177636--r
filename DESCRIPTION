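Package: tetrascan
Title: Windowed Tetranucleotide Signature Scanning of Genome Fragments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects compositionally exogenous regions in large-insert genome
    fragments (e.g. BAC or fosmid inserts from metagenomic libraries) by
    sliding-window tetranucleotide usage analysis. Windows are summarised by
    z-scores of observed 4-mer counts against a maximal-order Markov null, the
    pairwise Pearson correlation matrix of window signatures is computed, and
    runs of windows with anomalously low mean correlation are called as
    candidate laterally transferred regions. Also provides the computational
    half of 16S rDNA RFLP library screening (in-silico PCR with degenerate
    primers and restriction digestion), coding-density statistics, and a
    3rd-order Markov fragment simulator with implant truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
biocViews: Sequencing, Metagenomics, Software, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
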