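Package: memddm
Title: Single- and Dual-Process Diffusion Models of Memory-Based Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to compare a single-process diffusion model (a biased
    reference-value account) against a dual-process diffusion model (a
    utility/heuristic mixture account) of memory-based value decisions.
    Provides the two-boundary Wiener first-passage-time likelihood, trial
    simulators, a synthetic remember-and-decide data generator with known
    ground truth, preprocessing filters, hierarchical Bayesian estimation
    via an adaptive Metropolis-within-Gibbs sampler, qualitative
    response-time curve analyses with Savage-Dickey Bayes factors, WAIC
    model comparison, posterior predictive checks, and parameter and model
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
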