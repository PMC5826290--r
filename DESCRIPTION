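Package: catada
Title: Chromatin Accessibility Profiling Analysis for Targeted DamID
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for chromatin accessibility profiling by
    targeted DamID (CATaDa). Builds GATC fragment maps from genome
    sequence, converts mapped read positions to reads-per-million signal
    tracks at GATC-fragment resolution, calls accessibility peaks (runs
    of two or more consecutive fragments) with a permutation-based false
    discovery rate, intersects peaks across replicates and maps them to
    genes, identifies cell-type differential accessible regions and
    clusters them, nominates cell-type-specific enhancer candidates,
    tests interval-set overlaps by Monte Carlo simulation, summarises
    genome-wide accessibility distributions (low-accessibility band
    fractions, zero-read fractions, Welch/Games-Howell group
    comparisons), computes aggregation metaprofiles around TSS and
    interval sets, and generates fully synthetic genomes, annotations
    and read data with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
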