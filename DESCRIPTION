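Package: alignhush
Title: HMM-HMM Alignment with Hydrophobicity and Secondary-Structure Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Remote homology detection by pairwise alignment of profile
    hidden Markov models. Plan7 (HMMER2) profiles are re-encoded with
    per-column hydrophobicity and predicted secondary-structure
    frequencies, aligned locally by a five-state pair-HMM Viterbi
    procedure whose column score combines windowed conservation,
    hydrophobicity and secondary-structure terms, and scored
    statistically through per-query extreme-value (Gumbel) E-value
    calibration against a random profile database. Includes SCOP-style
    benchmark machinery (sensitivity/error-rate curves, developer and
    modeller alignment accuracy, parameter tuning) and a seeded
    synthetic-world generator so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
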