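Package: scaffpop
Title: Population Dynamics of Stem-Cell Aggregates on Electrospun Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compartmental ordinary-differential-equation model of human
    induced pluripotent stem cell aggregates cultured on melt electrospun
    scaffolds. Tracks stem, progenitor and differentiated cell populations
    together with local oxygen and waste (CO2 proxy) concentrations, with
    all transition rates modulated by environment-dependent effect
    functions of oxygen, waste and cell-scaffold contact. Provides
    closed-form, asymptote-approximate and numerically refined fixed
    points with Routh-Hurwitz and eigenvalue stability analysis,
    optimization of equilibrium populations over oxygen, waste and
    scaffold contact, gas-flux and aggregate-geometry utilities including
    conversion between imaged cluster area and cell number, named
    simulation scenarios, and a synthetic-data generator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
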