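Package: smoreglos
Title: Surrogate-Model Based Global Sensitivity Analysis for Agent-Based Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers global sensitivity indices of agent-based model (ABM)
    parameters by fitting explicit ordinary-differential-equation surrogate
    models to ABM ensemble output, quantifying surrogate-parameter uncertainty
    as hyperrectangles over ABM parameter space via profile likelihoods, and
    pushing standard global sensitivity methods (Morris elementary effects,
    extended FAST) through the surrogate instead of the expensive ABM. Includes
    a bundled 2D on-lattice cell-proliferation ABM with cell-cycle phases, a
    stochastic mock growth-curve generator, weighted least-squares surrogate
    calibration with multistart optimisation, profile-likelihood confidence
    bounds with a 0/1/2 identifiability index, AIC-based surrogate selection,
    multilinear confidence-hypersurface interpolation, and from-scratch
    Morris (MOAT) and eFAST engines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
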