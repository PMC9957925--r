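Package: osseodebond
Title: Adhesive-Frictional Debonding of Osseointegrated Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static, finite-strain finite-element simulation of
    bone-implant interface debonding. Implements a state-variable modified
    Coulomb friction law in which the friction coefficient interpolates
    between a bonded and an unbonded value through a smooth osseointegration
    state function, and its extension by an exponential cohesive zone model
    for normal adhesion and adhesion-shifted sliding. Includes Neo-Hookean
    hexahedral elements, penalty contact with master-slave closest-point
    projection, staged loading protocols, and ready-made coin-shaped-implant
    and acetabular-cup-implant removal scenarios with tidy response
    histories, peak-stability summaries and ggplot2 visualisation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
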