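Package: pspdigest
Title: Proline-Specific Peptidase Complexes and In Silico Gliadin Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying digestive proline-specific peptidase (PSP)
    complexes of tenebrionid insects and their action on glutamine- and
    proline-rich gliadin peptides. Implements a staged, rule-based digestion
    engine driven by peptidase substrate-specificity formulas (cysteine
    cathepsins, POP, DPP 4/8, PRCP, APP, XPD, LAP, CND), diagnostic-residue
    classification of candidate peptidase sequences against anchor profiles,
    single-linkage clustering of translated ORF blocks with consensus
    building, RPKM expression quantification with multiread and
    partial-alignment handling, and seeded synthetic-data generators so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
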