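Package: epmoran
Title: Death-Birth Moran Simulations with Shared Extended Phenotypes on
    Scale-Free Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An agent-based simulation platform for studying how extended
    phenotypes (nests, webs, dams and other outside-the-body gene effects)
    change the evolutionary dynamics of structured populations. Implements a
    modified Moran death-birth process on Barabasi-Albert scale-free graphs
    in which individuals of two competing types produce, use and share timed
    extended-phenotype tokens that modify reproductive fitness; a second
    engine adds a four-state behavioural cycle (searching, producing, using
    own, using other) with an own-use bonus alpha, a production cost beta and
    a shared-use bonus gamma. Provides the absolute-fitness algebra
    omega = alpha - beta + gamma, batch orchestration and parameter sweeps
    with reproducible seed schedules, an exact absorbing-Markov-chain
    fixation oracle for small graphs, plain-text edge-list and flat config
    file formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
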