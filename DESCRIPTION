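Package: sicore
Title: Synthesis Interactomes and Algorithmic Detection of Essential Cell Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents the synthesis of cellular elements as a table of
    commutative binary operators (a synthesis interactome), expands condensed
    synthesis formulas into binary expression trees, computes complete operand
    sets to a guaranteed fixpoint, classifies elements as essential when they
    are required for their own synthesis (recursion) or feed the synthesis of
    a recursive element (propagation), and reduces an interactome to its
    minimal essential core.  Every algebraic result is cross-checkable against
    an independent directed-graph formulation in which recursion corresponds
    to membership in a closed walk.  Includes in-memory fixtures (an RNA
    polymerase interactome and a small worked example), a seeded random
    interactome generator with planted cycles, tab-separated table readers
    and writers, and graph export to GraphML, DOT and edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
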