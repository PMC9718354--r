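Package: timerace
Title: Timed Racing Diffusion Models for Choice and Response-Time Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits racing diffusion models, with and without an internal
    timer accumulator, to trial-level choice and response-time data from
    two-alternative forced-choice (2AFC) perceptual tasks. Provides the
    Wald (inverse Gaussian) first-passage density and sampler, defective
    choice-RT likelihoods, differential-evolution MCMC posterior sampling
    under log-normal and inverse-logit priors, BIC-approximated Bayes
    factors for model comparison, a simulator of complete synthetic
    contrast-discrimination sessions (delay schemes, intertrial intervals,
    reward draws, real-time side-bias correction), and standard
    psychometric, chronometric and reward-rate summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
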