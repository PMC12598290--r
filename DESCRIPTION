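Package: seqbalance
Title: Library Quantification, Data Balancing and Run Planning for
    Large-Scale Multiplexed Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the production quality-control arithmetic of
    large-scale short-read whole-genome sequencing: relative
    quantification of multiplexed libraries from demultiplexed index
    ratios, initial-run-based data equalization (iDeal) that computes
    re-pooling volumes so cumulative per-sample read totals across
    flow cells come out even, cycle-budget and Lander-Waterman style
    yield and coverage planning, pooled-library sizing and molarity
    corrections for PCR-free libraries measured against RNA ladders,
    contamination and sequence-level QC filters, multi-sample mean
    coverage aggregation with accessibility classification, pedigree
    pair/trio/hepta-family enumeration from PED files, and a seeded
    simulator for end-to-end rebalancing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
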