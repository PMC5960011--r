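Package: bellcog
Title: CHSH Statistics, Symmetrization and Quantum Modeling of Bipartite
    Coincidence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-outcome bipartite coincidence experiments
    of the kind used in quantum cognition, such as the windrose
    (wind-direction) concept-combination experiment. Computes CHSH
    Bell-inequality statistics and marginal-law (no-signaling) residuals on
    4x4 joint-probability tables, implements the 180-degree and octahedral
    (eight-rotation) symmetrization protocols based on the participant
    consistency assumption, fits a singlet-state quantum model with product
    spin measurements to symmetric tables, provides the generalized rigid-rod
    (two elastic spheres) mechanical model with closed-form probabilities and
    a Monte-Carlo simulator, and generates synthetic respondent samples with
    bootstrap uncertainty for all statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
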