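Package: loopkin
Title: Activation and Friction Analysis of Protein Loop Opening and Closing Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the kinetics of protein loop conformational
    changes modelled as activated barrier crossing along a path collective
    variable. Provides a generalized Langevin simulator with exponential
    memory baths (Markovian embedding) emulating loop dynamics on model
    free-energy landscapes, order-parameter screening, string-method
    relaxation to the minimum free-energy path, umbrella sampling and WHAM
    reconstruction of the potential of mean force with block-bootstrap
    uncertainties, transition-state-theory rate constants and equilibrium
    constants, time-dependent friction kernels from projected-force
    autocorrelations, Grote-Hynes and Kramers transmission coefficients
    with friction-regime classification, transition-state trajectory
    shooting, and diffusive-displacement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
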