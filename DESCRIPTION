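Package: morphoclad
Title: Maximum-Parsimony Analysis of Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cladistic analysis of discrete morphological data:
    reading and writing character matrices (TNT/Hennig86 xread, NEXUS,
    plain table), Fitch/Hartigan parsimony optimization on binary and
    polytomous trees, heuristic search with random-addition Wagner trees
    and tree bisection-reconnection (TBR) swapping, ambiguous-branch
    collapsing, strict and majority-rule consensus, consistency and
    retention indices, nonparametric bootstrap support, sequential
    character-removal sensitivity analysis, and mapping of common
    unambiguous synapomorphies onto a consensus tree.  Ships the
    33-taxon x 67-character morphological matrix of the darkling-beetle
    tribe Helopini (Coleoptera: Tenebrionidae) as a worked fixture, and
    a seeded simulator of discrete characters evolving on a known tree
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
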