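Package: boutonsilence
Title: Single-Bouton Calcium Imaging Quantification and Synaptic Silencing Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies presynaptic function at single nerve terminals from
    time-lapse fluorescence recordings of genetically encoded sensors
    (synaptophysin-targeted GCaMP6f, vGLUT1-pHluorin, iGluSnFR). Detects
    bouton puncta, extracts background-corrected traces, converts GCaMP
    fluorescence to absolute intracellular calcium via a Hill-type sensor
    model, classifies terminals as silent or responding against baseline
    noise, and fits population dose-response relationships (linear
    x-intercept extrapolation of calcium influx versus external calcium,
    constrained Hill fit of silent fraction versus influx). Ships a
    ground-truth synthetic-data generator that renders punctate bouton
    movies and per-terminal traces so every analysis stage can be validated
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
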