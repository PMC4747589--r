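Package: mecell
Title: Mixed-Effects Modeling of Single-Cell Gene Expression Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attributes gene-expression model parameters to individual cells
    from time-lapse fluorescence trajectories of stimulated cell populations.
    Implements a two-state linear ODE model of inducible gene expression driven
    by a piecewise-constant stimulus signal, a log-normal mixed-effects
    population model, independent per-cell maximum-likelihood fitting ("naive"
    pooling), stochastic approximation EM (SAEM) estimation of the joint
    population distribution, maximum a posteriori estimation of single-cell
    parameters, population-level validation by resampling, and downstream
    single-cell analyses: parameter-feature correlations, PCA-based feature
    ranking, and bootstrap mother/daughter inheritance tests. A synthetic-data
    generator reproduces the statistical structure of repeated-osmotic-shock
    yeast microscopy experiments so the full pipeline is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
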