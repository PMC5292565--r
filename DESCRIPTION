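Package: vegfsig
Title: Rule-Based Modeling of VEGFR2 Signaling and Its Inhibition by TSP1/CD47
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates the VEGF-VEGFR2 receptor reaction network from
    site-graph interaction rules, couples it to coarse-grained ERK1/2 and
    calcium dynamics modules, and simulates inhibition of VEGF signaling by
    thrombospondin-1 (TSP1) acting through CD47. Includes a BNGL-subset model
    reader and SBML writer, stiff ODE simulation of timed stimulation
    protocols, derivative-free (pattern search) parameter fitting, global
    sensitivity analysis by partial rank correlation coefficients, dose-response
    and fold-change scan experiments with threshold detection, and a synthetic
    data generator for fitting and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    xml2,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
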