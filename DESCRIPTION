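Package: mlnsfa
Title: Maximum-Likelihood Non-Stationary Fluctuation Analysis of Synaptic Currents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates unitary currents, kinetic rate constants, the per-trial
    number of neurotransmitter-bound receptor channels and the peak open
    probability of synaptic receptor channels from sets of noisy macroscopic
    (postsynaptic) currents. The likelihood of a trace set under an aggregated
    Markov channel model with trial-to-trial quantal variability and coloured
    background noise is evaluated in near-linear time by exploiting the
    semiseparable structure of the single-channel covariance matrix.  Includes
    a stochastic macroscopic-current simulator (aggregated multinomial state
    counts plus AR(1)-sum noise), graduated multi-start maximum-likelihood
    fitting, bootstrap accuracy assessment, slice-sampling MCMC for
    single-trace likelihoods, and the peak-scaled non-stationary fluctuation
    analysis baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
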