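Package: splicedev
Title: Developmental Alternative Splicing Analysis from Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segment-based quantification of alternative splicing (percent
    spliced-in, PSI) from inclusion/exclusion junction counts, detection and
    classification of developmentally dynamic splicing with quasi-binomial
    generalized linear models over log developmental age, spline trajectory
    patterns (up, down, up-down, down-up), cross-species exon orthology by
    intersect-over-union graph components, intronic hexamer enrichment with
    Irwin-Hall cross-species p-value combination and PWM motif annotation,
    and parsimony dating of cassette-exon gain, loss and alternification on
    a species tree. Ships a synthetic multi-species developmental data
    generator with known ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    methods,
    igraph,
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
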