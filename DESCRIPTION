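Package: surrosp
Title: Covariate-Adjusted Measures of Surrogate Paradox Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures of the risk that a new clinical trial will exhibit the
    surrogate paradox -- a treatment that benefits a surrogate endpoint while
    harming the true endpoint -- computed from individual-patient
    meta-analytic data under a bivariate linear mixed model with patient
    covariates. Provides the covariate-conditional joint distribution of
    trial-level treatment effects, closed-form orthant-probability risk
    measures and their covariate-marginalized versions, conditional risk
    measures for an ongoing trial with partially collected data,
    surrogate-effect thresholds that bound the probability of a harmful true
    effect, a conjugate Gibbs sampler for fully Bayesian inference with
    posterior credible intervals, marginal WAIC for choosing between
    constant and trial-varying covariate effects, and a simulator with a
    bias/coverage replication study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
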