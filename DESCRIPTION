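Package: armsurvey
Title: Chromosome Arm Shotgun Survey Analysis and Genome Zipper Ordering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for low-coverage shotgun survey sequencing of
    flow-sorted Triticeae chromosome arms. Identifies repetitive reads by
    assembly depth and repeat-library masking, discovers conserved genes by a
    reciprocal-best-hit similarity filter cascade against model grass genomes,
    orders syntenic genes into a virtual gene map ("genome zipper") anchored
    by deletion-bin markers, detects chromosome rearrangements and putative
    lineage-specific translocations validated by read-coverage evenness,
    builds reference-guided coding-sequence models with transcript-coverage
    confidence classes, and computes closed-form survey statistics such as
    the base representation probability. Includes a synthetic-data generator
    that emulates a flow-sorted arm (purity, amplification duplicates, repeat
    content, planted rearrangements) with full ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
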