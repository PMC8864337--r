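Package: skewsphere
Title: Bayesian Inference for Skew-Rotationally-Symmetric Distributions on
    the Circle and Sphere
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Densities, exact samplers, and Bayesian inference for the
    skew Fisher-von Mises-Langevin family on the unit circle and sphere.
    Implements four prior scenarios with their posteriors and full
    conditionals, a sampling-resampling Gibbs algorithm that selects
    candidates drawn from the priors by their conditional-to-prior ratio,
    slice sampling for the non-conjugate location-concentration prior,
    loss-based Bayes estimators, a large-sample test of circular
    reflective symmetry, and a Wasserstein impact measure quantifying the
    influence of competing priors on the posterior.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
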