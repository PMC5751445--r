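Package: ssgc
Title: Semi-Supervised Graph Cut for Drug-Disease Treatment Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts drug-disease treatment relations by fusing drug and
    disease similarities from three data layers (chemical structure and
    disease phenotype, gene profiles, known treatments) and propagating
    sparse positive labels over an implicit weighted graph whose nodes are
    all drug-disease pairs. The pair graph is Kronecker-structured, so the
    propagation operator is applied without ever materializing the
    quadratic-size weight matrix. Includes a closed-form dense solver for
    verification, an HGBI-style self-loop propagation mode, positive-
    unlabeled ranking evaluation (modified ROC, top-percentile retrieval,
    guilt-by-association ratios), and a synthetic network generator with
    planted group structure for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
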