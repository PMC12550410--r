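Package: rnselect
Title: Bayesian Estimation of Nonlinear Selection on Reaction Norms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint Bayesian estimation of linear, stabilizing/disruptive and
    correlational selection on the parameters of individual reaction norms
    (intercept, environmental slope and residual predictability) for
    repeatedly measured labile traits.  A double-hierarchical mixed model for
    the phenotype is coupled with a quadratic fitness regression on latent
    individual reaction-norm deviations, so that uncertainty in the latent
    parameters propagates into selection inference (errors-in-variables).
    Posterior draws of the fitness-model coefficients are transformed into
    Lande-Arnold style directional and quadratic selection gradients by
    averaging derivatives of relative expected fitness over the population,
    with variance standardization.  Includes a generative simulator and a
    simulation-based validation workflow reporting bias, RMSD and the
    posterior probability of positive selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rjags,
    coda,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
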