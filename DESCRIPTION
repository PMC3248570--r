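Package: agnc
Title: Standardized Gene and Sequence Nomenclature for Anolis Lizards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the community nomenclature standards for the genus
    Anolis: generation and validation of four-letter species abbreviation
    codes with collision resolution against the canonical 378-species
    registry, derivation of Anolis gene and protein symbols from mammalian
    and avian orthologs, the additive transcript-evidence score, the
    colon-separated evolutionary character code (ECC) with its orthology
    relation classifier and taxonomic-span vocabulary, synteny
    flank-conservation counting against a reference gene order, and naming
    grammars for conserved sequences, short tandem repeats, and
    transposable elements. Includes a minimal perfect tandem-repeat
    scanner, seed-deterministic fixture generators, batch table
    processing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
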