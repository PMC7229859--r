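Package: votcaller
Title: Variable-Occupancy Target Region Detection from Replicated ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies cell-specific variable-occupancy target regions
    (VOTs) from replicated ChIP-seq peak sets of multiple protein targets.
    The genome is partitioned into fixed-width segments, replicate peak
    calls are reduced to a per-protein block reproducibility score,
    per-protein scores are aggregated into a reproducibility score matrix
    with a per-segment final score, and region counts at each score level
    are tested against a permutation null with a z-score. Includes
    downstream characterization (feature enrichment against shuffled
    controls, interval-overlap Fisher tests, dinucleotide composition,
    replicate clustering before and after removal of variable regions) and
    a seeded simulator of replicated multi-protein peak data with planted
    reproducible and variable blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
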