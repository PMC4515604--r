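Package: ahtpep
Title: Prediction, Screening and Design of Antihypertensive Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Length-stratified quantitative structure-activity (QSAR) modelling
    of antihypertensive (ACE-inhibitory) peptides. Dipeptides and tripeptides
    get support-vector regression of pIC50; peptides of four residues and
    longer get binary AHT/non-AHT classification, with models routed by a
    length category. Peptides are encoded by amino-acid composition, atomic
    (C/H/N/O/S and bond) composition derived from packaged molecular graphs,
    pluggable amino-acid scale matrices, or externally computed descriptor
    tables. Includes correlation-based feature selection with best-first
    search and backward (F-stepping) elimination, leave-one-out
    cross-validation with threshold-wise performance, analog design, library
    screening, protein window scanning, background negative sampling, and a
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
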