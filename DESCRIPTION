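Package: fsapminer
Title: Mining Secreted Peptides from Frog Skin Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering skin-secreted peptides of the frog
    skin active peptide (FSAP) superfamily from assembled transcriptome
    contigs. Finds and translates open reading frames, detects N-terminal
    signal peptides with a pluggable hydropathy heuristic, scans precursor
    proteins for prohormone-convertase cleavage motifs (KR, RR, RXXR),
    classifies acidic spacers, predicts mature peptides including
    glycine-donated C-terminal amidation, computes a physicochemical property
    panel (average and monoisotopic mass, formal net charge at pH 7,
    GRAVY, helicity), confirms peptides against LC-MS peak lists by
    theoretical ESI+ m/z matching, expands single-substitution variant
    libraries for sequence search, and summarises expression by protein
    family. Includes a seeded synthetic-transcriptome generator with known
    ground truth for end-to-end validation, plus closed-form broth-dilution
    MIC and neutral-red cytotoxicity calculations.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
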