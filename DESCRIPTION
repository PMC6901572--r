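Package: nmjelim
Title: Stochastic Vacancy-Mediated Competition Model of Synapse
    Elimination at the Neuromuscular Junction
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates developmental synapse elimination at the mouse
    neuromuscular junction as a stochastic spatial competition among
    motor-axon terminals, terminal Schwann cells (tSCs) and vacant
    territory on the muscle endplate.  Endplates are modelled as discs
    tiled by circular contact sites whose occupants evolve under a
    three-state Markov chain in which all axon-tSC exchange is mediated
    by vacancies; transition probabilities are solved in closed form
    from measured stationary area ratios.  Includes neighbour-weighted
    vacancy takeover, activity-biased site selection, alternative
    random- and equal-probability competition schemes, batch experiment
    runners (stage comparisons, activity sweeps, ratio sweeps with the
    composite-area correlation), a Dirichlet generator of synthetic
    per-endplate ratio profiles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
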