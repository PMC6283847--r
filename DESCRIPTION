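Package: glycoplan
Title: Programmable One-Pot Oligosaccharide Synthesis Planning with
    Predicted Building-Block Reactivities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans programmable one-pot syntheses of oligosaccharides from a
    library of thioglycoside building blocks with relative reactivity values
    (RRVs). Provides a glycan tree data model with an IUPAC-condensed text
    parser, perfect/precursor building-block matching against a query
    structure, depth-first search for RRV-ordered one-pot routes, hierarchical
    fragment decomposition with post-order fragment assembly scheduling, a
    support-vector regression model for predicting RRVs of virtual building
    blocks from structural features and ring NMR chemical shifts (with
    backward greedy wrapper feature selection), combinatorial enumeration of
    the virtual building-block library, and Tanimoto fingerprint screening
    against the validated library. Synthetic data generators with known
    ground truth make every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
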