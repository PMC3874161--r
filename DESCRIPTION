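Package: mitocodon
Title: Detection and Validation of Mitochondrial Sense-Codon Reassignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for discovering and validating natural
    sense-codon reassignment in small (mitochondrial) genomes. Implements
    codon-usage and liberated-codon analysis, conservation-based inference of
    codon identity from ortholog alignment columns, tRNA cloverleaf parsing
    and aminoacyl-tRNA synthetase identity-element classification, exact-window
    small-RNA read scans for tRNA processing and CCA maturation, variant-proteome
    construction with in-silico tryptic digestion and monoisotopic peptide mass
    matching, Michaelis-Menten aminoacylation kinetics, wobble-rule read sets
    with exact minimal anticodon-set computation, and a seeded synthetic-data
    generator so every stage is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
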