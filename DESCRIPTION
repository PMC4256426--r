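Package: tiegame
Title: Relation-Weighted Donation Games on Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates evolutionary donation games on undirected social
    networks in which cooperators allocate their investments across
    neighbors in proportion to tie strength raised to a preference
    exponent. Tie strengths are computed from the topological overlap of
    neighborhoods, with a configurable floor for edges without common
    neighbors. Provides synchronous Fermi-rule imitation dynamics,
    closed-form payoff analysis for mutual-best-friend pairs, graph
    readers and descriptive statistics, synthetic network generators
    (preferential attachment and clustered families), and a reproducible
    experiment runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
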