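Package: goodph
Title: Non-Invasive Raman pH Determination in Good-Buffered Systems
Version: 0.1.0
Authors@R: person("Good pH Probe", "Maintainers", email = "goodph@example.org",
    role = c("aut", "cre"))
Description: Determines the pH of MOPS-buffered aqueous systems from Raman
    spectra without touching the sample. Mixture spectra are evaluated by
    indirect hard modeling: pure-component models built from pseudo-Voigt
    peaks (water, protonated and deprotonated MOPS, optionally penicillin G)
    are co-fitted with a linear baseline, and the weight ratio of the two
    MOPS species is converted to a concentration ratio through a single
    ratiometric calibration factor. The pH follows from the
    Henderson-Hasselbalch relation with a temperature-dependent pKa.
    Includes complemental hard modeling for building solute models from
    binary aqueous spectra, leave-one-out cross-validation, an extended
    Debye-Hueckel diagnostic for ionic-strength effects, and a synthetic
    titration/enzyme-reaction simulator that provides ground-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
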