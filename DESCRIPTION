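Package: erythroscreen
Title: Simulation and Analysis of Flow-Cytometry Screens for Erythroid
    Enucleation Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate, gate and analyse 96-well flow-cytometry
    screens that measure erythroid enucleation, the extrusion of the
    nucleus by orthochromatic erythroblasts.  Provides an event-level
    simulator of drug-treated erythroblast wells with known ground truth,
    Ter119/Hoechst/CD44/PI gating, the net-enucleation statistic with
    plate-median normalisation and z-score hit calling, assay QC
    (Z'-factor, replicate correlation), and follow-up analyses: paired
    t-test validation, dose-trend testing, delay-versus-arrest mechanism
    classification, washout-recovery assessment and cytospin morphology
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
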