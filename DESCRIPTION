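Package: mitorder
Title: Mitogenome Architecture, Composition and Gene-Order Rearrangement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative characterization of annotated animal mitochondrial
    genomes: base composition, AT/GC strand skews, codon usage and relative
    synonymous codon usage (RSCU) under the invertebrate mitochondrial code;
    circular genome-architecture accounting (intergenic spacers, gene
    overlaps, strand tallies, category totals); and signed circular gene-order
    algebra with mechanistic rearrangement events (tandem
    duplication-random loss, inversion, translocation), bounded-depth
    scenario inference between gene orders, breakpoint distances,
    displaced-block decomposition against a reference arrangement, and a
    seeded simulator of crab-like mitogenomes and rearrangement histories.
    Reads and writes annotation tables, GenBank flat files, FASTA, and signed
    gene-order lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
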