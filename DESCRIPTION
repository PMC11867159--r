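Package: neutraldiv
Title: Neutral Phylogenetic Tree Models and Tree-Based Biodiversity Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and exact computation for neutral models of
    phylogenetic tree shape (Yule-Harding and uniform/PDA models, constant-rate
    birth-death processes with complete, reduced and evolutionary views), and
    for tree-based biodiversity measures built on them: phylogenetic diversity
    (PD), PD indices (fair proportion / evolutionary distinctiveness, equal
    splits, Shapley values), expected PD loss under field-of-bullets extinction
    at the present, a stochastic feature gain/loss model of feature diversity
    (FD), and the limiting proportions of PD and FD that survive an extinction
    event on large birth-death trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
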