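Package: qcpka
Title: Aqueous pKa Prediction from Quantum-Chemistry Thermochemistry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts aqueous acid dissociation constants (pKa) of
    para-substituted aniline radical cations and anilinium ions from
    quantum-chemistry output. Implements ideal-gas rigid-rotor
    harmonic-oscillator thermochemistry with two quasi-harmonic
    low-frequency corrections (frequency raising and harmonic/free-rotor
    entropy interpolation), direct and thermodynamic-cycle deprotonation
    free energies with solvation-protocol bookkeeping for implicit and
    explicit-water models, an embedded experimental benchmark dataset,
    benchmark statistics (RMSE and linear regression), and a synthetic
    species generator so the whole pipeline is testable without any
    electronic-structure calculation.
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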