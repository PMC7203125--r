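Package: giscreen
Title: Genetic Interaction Scoring for Arrayed Yeast Double-Mutant Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for colony-array genetic interaction screens of
    budding-yeast double mutants. Fits linear colony growth rates from plate
    time courses, normalizes to in-plate wild-type controls, corrects edge
    effects, filters technical outliers within quadruplicates, and computes
    multiplicative fitness (W) and genetic interaction (epsilon) scores with a
    histogram-mode consensus across biological replicates. Calls synthetic
    lethality from replicated binary growth with parent quality-control
    exclusion, estimates false-negative and contamination rates from sentinel
    plate positions, reconciles screen results with curated evidence into
    confidence classes, and includes a full synthetic screen generator so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
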