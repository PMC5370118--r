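Package: bgflux
Title: Landscape and Flux Analysis of the Basal Ganglia-Thalamo-Cortical Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a seven-population firing-rate model of the basal
    ganglia-thalamo-cortical motor circuit and the non-equilibrium
    potential-landscape and curl-flux machinery used to analyse Parkinsonian
    beta-band oscillations. Provides deterministic integration, fixed-point
    and limit-cycle analysis across dopamine levels, a Gaussian moment
    closure of the stochastic dynamics, construction of two-dimensional
    potential landscapes U = -ln P and probability flux fields, scalar
    stability metrics (barrier height, average flux along the cycle, entropy
    production rate), global sensitivity analysis of circuit wiring, and
    in-silico deep-brain-stimulation protocols, together with a brute-force
    Langevin simulator used as an independent oracle.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
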