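Package: topoqspr
Title: Degree-Based Topological Indices and QSPR Regression for Drug Sets
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes nine degree-based topological indices (first and
    second Zagreb, modified second Zagreb, harmonic, forgotten,
    hyper-Zagreb, symmetric division, and the first and second revised
    Randic indices) on hydrogen-suppressed molecular graphs built from
    SMILES strings or explicit heavy-atom edge lists, and fits simple
    linear quantitative structure-property relationship (QSPR) models
    relating those indices to measured physicochemical properties.
    Ships a curated benchmark set of twenty ophthalmic anti-infective
    drugs with six experimental properties and reference index values,
    together with a validator that reconciles computed indices against
    the reference table and a command-line interface for batch index
    calculation, QSPR fitting, and fixture validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
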