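Package: ergthresh
Title: Electrophysiology Waveform Scoring and Piecewise Threshold
    Dose-Response Estimation
Version: 0.1.0
Authors@R:
    person("Ohio", "Vision Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring flash electroretinogram (ERG) and flash
    visual evoked potential (fVEP) waveforms into standard clinical
    endpoints (a-wave, b-wave, oscillatory potentials and their sum,
    photopic negative response, flicker amplitude, N1-P1 metrics), and
    for estimating mechanical injury thresholds from dose-response data
    with a piecewise linear (hinge) threshold regression fitted over a
    grid of postulated threshold pairs, with F-test inversion, contour
    probability surfaces and multi-alpha threshold selection.  Includes
    a fully seeded synthetic-data generator (waveform sweeps with
    planted components; dose-response tables with known thresholds,
    slopes and noise) so that every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    digest
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
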