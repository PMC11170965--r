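Package: oligocodec
Title: Constraint-Aware DNA Data Storage Codec with Pin-Keyed Rule Permutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encode arbitrary byte streams into synthesizable DNA strings and
    decode them back, including from noisy, incomplete sequencing reads. The
    codec maps 4-bit coding units to dinucleotides through a pair of secret
    permutation rules (a "codec pin") drawn from the 16!-sized rule space,
    screens every emitted string against regional GC-content and homopolymer
    constraints, protects fragments with per-fragment Reed-Solomon parity and
    one-third XOR erasure redundancy, designs PCR random-access flanking
    primers, and reconstructs stored files from sequencing reads via a
    filter/rank/cluster/select pipeline. Includes a seeded read simulator and
    windowed sequence statistics for evaluating encoded pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
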