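Package: dgfus
Title: Displacement-Guided Focused Ultrasound Monitoring Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipelines for mechanistic monitoring of focused
    ultrasound (FUS) neuromodulation experiments in rodents: delay-and-sum
    beamforming and coherent compounding of plane-wave RF channel data,
    speckle-tracking estimation of acoustic-radiation-force brain
    displacement by 1D normalized cross-correlation, SVD clutter filtering
    into power-Doppler cerebral blood volume (CBV) time series,
    lag-resolved stimulus-correlation activation maps, EMG envelope and
    compound-muscle-action-potential peak detection, paw-keypoint
    kinematics, open-field zone analysis, and the cross-modal statistics
    linking displacement, CBV and motor readouts.  A seeded synthetic-data
    generator (scatterer phantoms with radiation-force pushes and
    stimulus-modulated blood signal, EMG traces, keypoint and open-field
    trajectories) provides ground-truth inputs for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
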