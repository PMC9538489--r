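Package: memmech
Title: Mechanical and Interfacial Analysis of Model Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the physicochemical characterization of
    model lipid membranes built from natural lipid extracts. Fits
    Gibbs-Langmuir adsorption isotherms of surfactant solutions (maximum
    surface concentration, adsorption constant, critical micelle
    concentration, mean molecular area), processes Langmuir-trough
    compression isotherms (compressibility-modulus profiles, lift-off and
    collapse detection), extracts lateral diffusion coefficients from
    fluorescence recovery after photobleaching (FRAP) traces, derives
    bending moduli from micropipette-aspiration experiments on giant
    unilamellar vesicles in the entropic (low-tension) regime, and
    quantifies lipid composition from thin-layer-chromatography
    densitometry together with phosphorus standard-curve calibration and
    vesicle-population statistics. A seeded synthetic-data generator
    emulates every supported input type with known ground truth so that
    each analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
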