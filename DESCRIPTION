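Package: hmucall
Title: Single-Base Resolution Calling of 5-Hydroxymethyluracil from
    Chemical-Conversion Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of chemical-conversion sequencing of
    5-hydroxymethyluracil (5hmU). Oxidation of 5hmU to 5-formyluracil
    followed by polymerase extension induces T-to-C base changes in
    sequencing reads; this package simulates converted amplicon and
    genome-style data with a matched no-oxidation control, derives
    per-site base-composition signals from reads or count tables, calls
    modified sites with a one-sided exact test against the control under
    Benjamini-Hochberg FDR control, characterises detection limits over
    incorporation-level titrations and trinucleotide sequence contexts,
    and tests overlap of called sites with enrichment-derived regions by
    permutation over candidate T positions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
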