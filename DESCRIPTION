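Package: fossilplace
Title: Backbone-Constrained Fossil Placement by Implied-Weights Parsimony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Places a single fossil taxon on every branch of a fixed molecular
    backbone tree and scores each candidate attachment by implied-weights
    parsimony on a discrete morphological character matrix, reporting optimal
    and suboptimal placements as a ranked table and a branch-annotated Newick
    tree. Includes a NEXUS-dialect reader/writer that preserves the distinction
    between missing ('?'), inapplicable ('-') and polymorphic ('{..}') cells, a
    Fitch/Hartigan small-parsimony engine with Goloboff concave weighting, and
    a seeded Mk-model simulator (Yule trees, discrete characters, fossil-style
    missingness) for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
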