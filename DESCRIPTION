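Package: lossguard
Title: Quantifying Falsely Inferred Gene Absences in Eukaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how incorrect gene prediction inflates
    gene-loss estimates in eukaryotes. Reconstructs ancestral (LECA) protein
    domain content on a rooted species tree with Dollo parsimony, classifies
    domain absences as clade- or species-specific, verifies absences against
    six-frame translated genomes with a stop-codon pseudogene filter, and
    recounts losses after rescuing absences that are present in the DNA.
    Includes a synthetic-data generator with planted gain/loss histories and
    detection failures so the whole pipeline can be exercised against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
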