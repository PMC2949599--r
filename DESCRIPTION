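Package: solenoidal
Title: Solenoidal Coordinate Method for Periodicity Detection in Sparse
    Site Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects periodic patterns in sparse boolean sequences, such
    as gene start positions along a chromosome. Candidate periods are
    screened by wrapping the support around a periodic solenoid and
    scoring the clustering of the projected sites with exact circular
    order-statistics spacing laws; scores are calibrated against a
    Monte-Carlo uniform null to give a p-valued spectrum that is robust
    to positional noise, missing sites and contamination, and per-site
    positional scores identify which sites participate in each
    periodicity. Includes pair-distance histogram and autocorrelation
    baselines, synthetic scenario generators, readers for plain
    position lists, BED and GFF3, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb
Config/testthat/edition: 3
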