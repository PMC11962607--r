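Package: diatomglide
Title: Kinematics, Behavioral States, and Stochastic Simulation of Diatom Gliding Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell tracking of benthic diatom
    gliding motility. Reads centroid/orientation tracking tables, computes
    frame-wise kinematics (tangential and normal velocity, rotation rate),
    estimates track and raphe curvature by arclength resampling and
    moving-window three-point circle fits, segments each trajectory into the
    four stereotyped behavioral states (Glide, Reverse, Pivot, Stop),
    estimates a four-state continuous-time Markov transition model with
    per-state dwell-time distributions, calibrates an eight-parameter
    state-switching Langevin model per species, and simulates 2D and 3D
    trajectories with a hybrid Gillespie-Langevin scheme to predict long-time
    dispersal (mean squared displacement, velocity autocorrelation,
    macroscopic diffusivity). Includes a synthetic-data generator with a
    measurement model (localization noise, ellipse-orientation ambiguity) for
    end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
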