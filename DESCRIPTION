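Package: bisir
Title: Bidirectional-Immunization SIR and SIS Epidemic Models on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for an SIR (and SIS) epidemic model with bidirectional
    immunization: vaccination reduces the infection rate of susceptibles by a
    factor (1 - delta) while clinical treatment raises the recovery rate of
    infecteds by a factor (1 + lambda), with demographic turnover through a
    birth rate b and a natural death rate d. Provides degree-based mean-field
    equations for homogeneous and heterogeneous contact networks with numerical
    integration, closed-form basic reproduction numbers and outbreak
    thresholds, endemic-equilibrium analysis via a self-consistency equation, a
    finite birth-death continuous-time Markov chain formulation (transition
    probability and generator matrices, stationary distribution, embedded
    chain) with exact Gillespie sampling, and discrete-time Monte-Carlo
    simulation on explicit contact graphs (Erdos-Renyi, Barabasi-Albert, or
    user-supplied edge lists) including immunization sweeps and epidemic
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
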