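Package: pigatria
Title: Ionic Model and Tissue Simulator for Pig Atrial Electrophysiology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An ionically detailed model of the porcine atrial cardiomyocyte
    (12 membrane currents with Hodgkin-Huxley gating, a calcium-activated
    chloride transient outward current, and Luo-Rudy sarcoplasmic-reticulum
    calcium handling) together with the experimental protocols used to
    characterise it: voltage-clamp IV curves, pacing restitution, effective
    refractory period measurement, monodomain cable and sheet simulation with
    forward-time centred-space numerics, S1-S2 cross-field spiral initiation,
    spiral-tip tracking, signed-frequency trajectory spectra, phase-singularity
    counting and alternans detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
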