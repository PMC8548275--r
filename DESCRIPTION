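Package: rachis
Title: Hydraulic Analysis of Germ Cell Volume Homeostasis in a Syncytial Gonad
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of tissue hydraulics in the
    syncytial C. elegans germline: detection of the unimodal-to-bimodal
    transition in germ cell volume distributions (slope-break, Hartigan dip
    and Gaussian-mixture criteria), particle image velocimetry and
    axisymmetric integration of cytoplasmic fluxes through the rachis,
    flux-balance inference of the germ-cell-to-rachis current and of material
    uptake from the surrounding tissue, a steady-state one-dimensional
    two-phase pressure-flow model with parameter fitting, and the two-balloon
    (doublet) instability model with its effective potential, linear
    stability analysis and bifurcation diagram along the gonad axis. A
    seeded synthetic-data generator emulates all required inputs, and a
    pipeline driver ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
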