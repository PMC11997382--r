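Package: cmdnirs
Title: Detecting Cognitive Motor Dissociation from fNIRS Motor-Imagery Recordings
Version: 0.1.0
Authors@R:
    person("Avery", "Collins", email = "avery.collins@example.org",
           role = c("aut", "cre"))
Description: A tested, re-usable pipeline for detecting covert command-following
    (cognitive motor dissociation, CMD) in disorders-of-consciousness patients
    from block-design motor-imagery fNIRS recordings. Converts raw
    multi-wavelength light intensity to oxy-/deoxyhemoglobin concentration
    changes (coefficient-of-variation channel rejection, optical density,
    sliding-window motion-artifact correction with cubic-spline subtraction,
    zero-phase 0.01-0.1 Hz band-pass, modified Beer-Lambert law), block-averages
    region-of-interest responses, extracts seven hemodynamic features per
    chromophore, trains RBF support-vector machines on healthy controls with
    genetic-algorithm hyperparameter search, renders per-patient
    command-following decisions, and performs exact 2x2 contingency inference
    on diagnostic accuracy and outcome. Includes a synthetic-cohort generator
    with known ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
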