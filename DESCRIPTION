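Package: nbsmotif
Title: Search for Shared RNA Stem-Loop Motif Architectures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural motifs shared between a reference and a target
    RNA without sequence alignment. Locally stable secondary structures of the
    reference are decomposed into non-branching structures (NBSs, single
    stem-loops), encoded as an ordered secondary structure descriptor (SSD) of
    sequence-structure patterns, matched against the target under the RNA base
    pairing rules (including GU wobble), and chained by dynamic programming
    with a score that rewards long runs of NBSs at reference-consistent
    spacings. Supports a unique-structure mode and an overlapping
    alternative-structures mode, shuffle-based significance (z-scores and
    empirical p-values), family-ranking evaluation, and a synthetic
    planted-motif data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
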