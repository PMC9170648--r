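Package: varwithin
Title: Bayesian Tests of Homogeneous Within-Person Variance and Varying
    Reliability in Mixed-Effects Location-Scale Models
Version: 0.1.0
Authors@R:
    person("Ava", "Doyle", email = "ava.doyle@example.org",
           role = c("aut", "cre"))
Description: Fits mixed-effects location-scale models (MELSM) to long-format
    repeated-measures data and tests the assumption of a common within-person
    variance with Dirac spike-and-slab model comparison.  Two tests are
    provided: a global test on the between-person standard deviation of the
    scale (log-variance) random intercepts, and a membership model that
    classifies which individuals share the common within-person variance.
    Posterior model probabilities from transdimensional MCMC yield Bayes
    factors, and individually varying intraclass correlation coefficients
    quantify person-specific measurement reliability.  Includes a synthetic
    trial-data generator with the model's exact statistical structure, a
    reaction-time cleaning rule, prior-sensitivity grids, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    coda,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    yaml,
    withr,
    ggplot2
Config/testthat/edition: 3
NeedsCompilation: yes
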