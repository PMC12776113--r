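Package: dupdel
Title: Parent-Child Assignment and Feature Analysis of Duplicate Gene
    Deletion Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for duplication-then-deletion events in
    Drosophila gene pairs. Assigns parent (ancestral) and child (derived)
    labels to the survived/lost copies of each deletion event through a
    six-stage evidence cascade (literature flags, 12-species conservation,
    retrotransposition via intron structure, 37-species ortholog counts,
    orthogroup sizes, and derived-copy conservation), tests for biased loss
    of parents versus children with exact two-sided binomial tests, and
    compares sequence rate, expression, protein-interaction degree, and
    structural features across single-copy, deleted-redundant, and
    deleted-unique gene groups with two-sided Mann-Whitney U tests. Includes
    a synthetic cohort generator with planted ground truth so that the full
    pipeline runs and is testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
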