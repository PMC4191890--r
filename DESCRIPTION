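Package: termscan
Title: Mapping RNA Polymerase II Termination Regions from Strand-Specific
    Occupancy Tracks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps in vivo RNA polymerase II termination regions from
    strand-specific per-base occupancy tracks (e.g. PAR-CLIP of Pol II)
    measured with and without nuclear depletion of a termination factor.
    Computes a per-position Readthrough Index from 500-bp flanking-window
    occupancy fractions, refines candidate regions to single termination
    points by spline fitting of the control-minus-depleted difference
    profile, selects unambiguous polyadenylation-site anchors, builds
    anchor-centered metagene profiles and percent-readthrough rankings, and
    analyses terminator sequence content (Nrd1/Nab3 motif scanning, U-run
    statistics, dinucleotide-shuffle enrichment). Includes a synthetic-data
    generator that emulates the occupancy structure of factor depletion
    (processive Nrd1-type readthrough, short Sen1-type readthrough,
    confined Ysh1-type 3'-pileups) with known ground truth, plus readers
    and writers for bedGraph, fixed-step wiggle, BED and FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
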