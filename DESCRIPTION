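Package: ecaflux
Title: Kinetic Modelling of Extracellular Acidification Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-equation modelling of cellular glucose catabolism as read out
    by kinetic extracellular acidification (ECA) plate-reader assays. Implements
    a seven-reaction capacity-limited mass-action network linking extracellular
    glucose, glycolysis, lactate export and a lumped mitochondrial branch;
    stiff ODE simulation of the two-phase ECA response; drug-modulation
    (oligomycin, 2-deoxyglucose) dose sweeps; one-at-a-time sensitivity
    analysis; calibration of the model to normalized plate-reader curves via
    profiled-affine least squares with bounded multistart optimisation; a
    synthetic plate-reader data generator for parameter-recovery testing; and
    SBML Level 3 Version 2 model exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
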