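Package: biosensr
Title: Characterization of Small-Molecule Biosensors from Plate-Reader
    and Flow-Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for characterizing genetically
    encoded small-molecule biosensors (allosteric transcription factors
    driving fluorescent reporters). Provides growth-normalized expression
    kinetics from plate-reader time courses, promoter-activity transfer
    functions fitted with a Hill model extended for basal and maximal
    expression, fold-induction with exact error propagation and
    lower-bound rules, inducer toxicity normalization, cross-reactivity
    and orthogonality analysis, multi-channel flow-cytometry state
    classification, and sensor-based enzyme-variant screening. A
    synthetic-data generator emulates the plate-reader and cytometry
    experiments (lagged logistic growth, Hill-regulated per-cell reporter
    production, measurement noise, dose-dependent growth inhibition,
    growth-phase-dependent expression shutoff, lognormal single-cell
    fluorescence) so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
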