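Package: sepgraph
Title: Socioecological Process-Graph Analysis of Agroecosystem Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing socioecological process graphs
    (SEP-graphs): bipartite networks in which species, resources, states and
    ecosystem services are material-type nodes and ecological processes or
    interactions are operating-unit-type nodes. Implements the five structural
    axioms of process network synthesis, maximal structure generation (MSG),
    exhaustive solution-structure generation (SSG), and linear-programming
    flow optimisation with accelerated branch-and-bound (ABB) ranking of
    feasible sub-networks. Ships a worked agroecosystem case study of a potato
    farm threatened by the Colorado potato beetle (Leptinotarsa decemlineata),
    with chemical and biological pest-control scenarios, plus a seeded random
    instance generator for validating the algorithms against brute-force
    enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
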