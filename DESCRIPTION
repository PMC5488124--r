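Package: modcon
Title: Modular Construction, Validation and Simulation of Compartmental Model Code
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pre-compiler for declarative physiological model code. Model
    fragments (flow, passive exchange, chemical reactions, convection) are
    archived as named modules in annotated plain-text libraries; directive
    lines embedded in a constructor file select modules, rename their
    variables and parameters, replicate template lines over species and
    compartments, and merge per-process differential-equation contributions
    into combined rate equations for a complete model file. The package also
    provides structural validation of generated models, a fixed-step
    Runge-Kutta interpreter for the ordinary-differential-equation subset
    (including the lagged normal density inflow function used in
    indicator-dilution experiments), and generators of synthetic
    species-by-region model families for scaling tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    deSolve,
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
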