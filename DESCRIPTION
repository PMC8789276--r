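Package: divlab
Title: Invasion Analysis of Reproductive Division of Labour in Structured Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking when a clonal group of uniformly cooperating
    cells can be invaded by a mutant that divides labour between highly
    cooperative helpers and weakly cooperative reproductives. Cells sit on an
    undirected group graph (filament, branching growth, well-mixed, or
    user-supplied), produce a public good H(z) at fecundity cost F(z), and
    share a fraction lambda of the good equally among direct neighbours. The
    package computes the uniform evolutionarily stable cooperation level,
    classifies invasion by a second-order expansion of group fitness into
    three routes (accelerating returns, between-individual differences,
    reciprocal specialisation), evaluates the spectral sparse-network
    condition lambda * mu > d for degree-regular groups, analyses random
    (uncoordinated) role assignment, and sweeps shareability-by-return-shape
    phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
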