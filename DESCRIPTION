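Package: hsp70typer
Title: Signature-Based Typing of Heat-Inducible Hsp70 Family Members
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining heat-inducible members of the Hsp/Hsc70
    chaperone family in amphipods and other non-model arthropods from
    sequence evidence alone. Provides degenerate protein signature scanning
    and a rule-based Hsp70/Hsc70 classifier, detection of heat shock
    elements (alternating NTTCN/NGAAN pentamer runs) in promoter DNA with
    distances upstream of the ORF start, open reading frame finding and
    translation, pairwise identity and per-column conservation/consensus
    analysis of protein alignments, candidate filtering of differential
    expression result tables, and a qPCR delta-Cq pipeline with exact
    Wilcoxon-Mann-Whitney tests and Holm correction. Deterministic
    synthetic-data generators emulate every input so the complete workflow
    runs and is tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
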