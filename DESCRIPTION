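Package: pprfret
Title: Single-Molecule FRET Analysis of Designer PPR Protein RNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of two- and three-color single-molecule
    FRET trajectories reporting the conformational compaction of designer
    pentatricopeptide repeat (PPR) proteins upon single-stranded RNA binding.
    Provides a continuous-time Markov trace simulator with photobleaching and
    donor-to-acceptor crosstalk, crosstalk calibration and FRET computation,
    nonlinear forward-backward trace denoising, Gaussian hidden Markov model
    state finding with model selection, dwell-time and binding-kinetics
    extraction with censoring rules, alternating-laser-excitation (ALEX)
    three-color coincidence analysis, alpha-solenoid superhelical geometry
    (rise, twist, pitch, radius, inter-repeat hinge screws, FRET-pair
    screening), and 1:1 ligand-depletion binding-isotherm fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
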