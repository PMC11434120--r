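Package: cdpmine
Title: Deep Mining of Cyclic Dipeptides from LC-MS/MS Molecular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation of cyclic dipeptides (2,5-diketopiperazines) and small
    peptides in feature-based molecular networks from LC-MS/MS experiments.
    Provides monoisotopic formula arithmetic and an amino-acid residue library
    including unnatural residues (4-hydroxyproline, glutamate 5-methyl ester,
    pyroglutamate), prediction of diagnostic fragment ions (immonium ions,
    neutral losses, b/y ions), exact-mass candidate enumeration, evidence
    scoring against MGF spectra, annotation propagation across network edges
    via residue-exchange mass deltas, reconciliation of de novo dipeptide
    calls with their cyclic forms, retention-time based isomer classification,
    and a seeded synthetic-data generator producing MGF spectra and
    node/edge/ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
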