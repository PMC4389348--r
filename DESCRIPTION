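Package: condact
Title: Conditional Activity Analysis of Cooperative Binding Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build microstate models of coupled transcription-factor binding
    sites, compute equilibrium occupancies from additive free energies
    (Shea-Ackers style thermodynamic models), derive detailed-balance
    continuous-time Markov chain kinetics, and quantify temporally-correlated
    (non-Markovian) binding fluctuations with the conditional activity, a
    waiting-time correlation function. The conditional activity is computed
    both from binding-event time series (simulated with the exact Gillespie
    algorithm, or experimental) and analytically from the transition-rate
    matrix via absorbing-chain fundamental matrices. Ships the phage lambda
    lysogeny/lysis switch as the flagship model instance together with
    mutual-information and entropy diagnostics of its binding-site network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
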