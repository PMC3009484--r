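Package: pairedLCA
Title: Taxonomic Binning of Paired Metagenomic Reads by Combined Bit Scores
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the lowest-common-ancestor (LCA) gene-content
    algorithm for taxonomic binning of shotgun metagenomic reads, including
    a paired-reads mode in which bit scores of the two mates of a clone are
    merged per reference organism using a Karlin-Altschul pair-sum
    correction before filtering. Provides the three standard match filters
    (min score, top percent, min support), clade exclusion for
    unknown-species experiments, a MetaSim-style simulator of synthetic
    communities, clone libraries, Illumina 75 bp paired reads with a fitted
    exponential positional substitution profile and flow-cycle 454-like
    reads, a BLAST-free synthetic match-table generator, and an evaluation
    suite (species detection, rank histograms, same-gene co-hit fraction,
    correct-assignment rates, min-support sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
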