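Package: kurafit
Title: Validation of Delay-Coupled Phase-Oscillator Whole-Brain Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates resting-state brain activity with a Kuramoto network of
    delay-coupled, noise-driven phase oscillators built on structural
    connectomes, and fits the simulated functional connectivity (FC) to
    empirical FC by tuning global coupling, delay and noise intensity.
    Provides the Pearson goal function, a dense grid-search baseline, four
    derivative-free optimizers (Nelder-Mead, particle swarm, CMA-ES and
    Gaussian-process Bayesian optimization), and benchmarking machinery:
    success-probability resampling, a multiplicative five-component cost
    function and per-subject method recommendations. A synthetic-cohort
    generator emulates the statistical structure of connectome and BOLD data
    so the whole pipeline can be exercised and tested without access to
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
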