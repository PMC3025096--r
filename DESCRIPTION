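Package: lensphos
Title: Label-Free Phosphoproteomics Quantitation and Phosphosite Cataloging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative shotgun phosphoproteomics of a two-condition
    design (e.g. normal versus cataractous eye lens): peptide monoisotopic mass
    and m/z computation with positioned variable modifications, in-silico
    tryptic digestion and phosphosite-to-protein position mapping, target-decoy
    false-discovery-rate estimation for peptide-spectrum matches, label-free
    quantitation by retention-time alignment and extracted-ion-chromatogram
    (XIC) area integration with cross-assignment between runs, phosphosite
    catalog validation and summary statistics (residue distributions, novelty
    and differential classification), and a seeded synthetic LC-MS experiment
    generator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
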