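Package: trinetlab
Title: Subnets, Trinets, and Equivalence of Rooted Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rooted phylogenetic networks: induced subnets via
    lowest stable ancestors, trinet enumeration, equivalence and
    network-equivalence testing through canonical forms, displayed-tree
    enumeration, and constructions of paired nonbinary and binary networks
    that are not equivalent yet induce identical subnets on every proper
    leaf subset. Includes extended Newick (eNewick) input/output, DOT
    export, a seeded random-network generator, and a command-line driver
    for machine verification of the pairs' properties at small leaf counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
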