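Package: mitochar
Title: Characterisation of Annotated Circular Mitochondrial Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising annotated circular mitochondrial
    genomes of vertebrates: gene tables with circular spacer/overlap
    arithmetic and start/stop codon classification, strand-skew base
    composition (AT-skew, GC-skew), relative synonymous codon usage
    (RSCU) under the vertebrate mitochondrial code, per-gene Ka/Ks
    estimation by the Nei-Gojobori (1986) pathway method with
    Jukes-Cantor correction, genus-monophyly assessment on phylogenetic
    trees, and seeded synthetic-data generators (annotated genomes and
    codon alignments with known truth) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
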