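Package: synquant
Title: Bayesian Quantal Analysis and Nested-Data Statistics for Synaptic
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates synaptic quantal parameters (number of release sites,
    quantal size, uniquantal coefficient of variation, per-condition release
    probabilities) from evoked postsynaptic response amplitudes recorded under
    multiple release-probability conditions, using a binomial-gamma quantal
    model with exact Bayesian inference on a discrete (n, log q, log gamma)
    grid. Also provides the derived electrophysiological measures used
    alongside quantal analysis (synaptic and recurrent-inhibition
    conductances, driving-force IPSP correction, stimulus-artifact
    subtraction, response kinetics, onset latency, paired-pulse ratio,
    miniature-event detection), a forward simulator of the quantal model for
    validation, and a statistics toolkit for nested electrophysiology data
    (one-way random-effects ICC, bootstrapped mean difference and Hedges' g,
    two-level hierarchical bootstrap, analysis-path routing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
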