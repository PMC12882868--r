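Package: mybfunnel
Title: Genome-Wide R2R3-MYB Identification and Co-Expression Candidate
    Prioritization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies R2R3-MYB transcription factors in a proteome by
    position-specific scoring of the MYB repeat and filtering on the
    N-terminal two-repeat architecture, names family members by chromosomal
    order and detects tandem-duplication clusters from gene models, assigns
    phylogenetic subgroups with a trimmed alignment, neighbor-joining tree
    and reference-labeled sequences, and prioritizes lignin/tricin-regulator
    candidates through expression-atlas co-clustering with a reference
    "lignin toolbox" gene set, internode developmental-zone profiling,
    Pearson co-expression screening with functional-category counting, and
    qPCR/dual-luciferase validation statistics. Ships a synthetic-data
    generator that plants known repeats, tandem arrays, co-expression
    clusters and effect sizes so the whole funnel is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    phangorn,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
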