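Package: predstat
Title: Markov Sequence Learning: Design, Simulation and Strategy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying statistical learning of probabilistic temporal
    sequences. Defines k-th order Markov stochastic sources over small symbol
    alphabets, characterizes them by entropy rate and predictive complexity
    (past-future mutual information), generates and selects presentation
    sequences by Kullback-Leibler divergence to the source, builds the
    trial/block structure of a serial prediction experiment, simulates
    responders that interpolate between uniform guessing, probability matching
    and maximization with lapse noise and a learning time course, and scores
    responses with the distribution-overlap Performance Index and the
    matching-versus-maximization strategy statistics (per-block Delta-KL
    strategy choice and the integrated strategy index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
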