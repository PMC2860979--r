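Package: barcodiag
Title: Distance- and Character-Based Species and Form Discrimination from
    Multi-Locus DNA Barcode Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating closely related species and
    intraspecific forms from aligned multi-locus DNA sequence data.
    Computes IUPAC-aware uncorrected p-distances with pairwise deletion,
    per-group-pair mean and standard-deviation summaries, mismatch
    distributions of pairwise distances with barcoding-gap detection,
    and character-based diagnostics that classify alignment columns as
    purely diagnostic or private for each group, with specimen assignment
    from pure diagnostic sites. Includes a Jukes-Cantor-based multi-locus
    simulator that reproduces a configurable four-group divergence
    hierarchy for testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
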