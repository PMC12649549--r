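Package: permamp
Title: Cyclic Sequence Permutation Design and Selectivity Scoring for
    Antimicrobial Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing antimicrobial peptide (AMP) variants by
    cyclic sequence permutation and for scoring their selectivity from
    standard wet-lab assay tables. Generates rotation libraries that
    preserve amino-acid composition while reordering the sequence, computes
    sequence-order-sensitive physicochemical descriptors (helical-wheel
    hydrophobic moment, Guruprasad instability index) alongside composition
    descriptors (GRAVY, mean hydrophobicity, aliphatic index, net charge,
    molecular weight), parses censored two-fold-dilution MIC panels,
    summarises them as geometric means with a fixed substitute for
    ">50"-style cells, estimates HC10 from hemolysis dose-response curves,
    and reports therapeutic indices (HC10/GM) stratified by Gram stain.
    A seeded synthetic-assay generator emulates the dilution-grid MIC
    readout and saturating hemolysis and calcein-leakage curves so the full
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
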