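Package: respfs
Title: Metaheuristic Wrapper Feature Selection for Respiratory Sound Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for binary metaheuristic feature
    selection on audio-derived feature tables, motivated by respiratory
    disease classification from lung-sound recordings. Six population-based
    optimizers (GA, PSO, GWO, TLO, WOA, EO) are discretized by eight S- and
    V-shaped transfer functions and driven by an imbalance-aware wrapper
    fitness combining the Matthews correlation coefficient of a KNN
    classifier with a subset-size penalty. Includes a 75-dimensional audio
    summary-feature extractor (chroma, MFCC, spectral descriptors pooled by
    five statistics), classical filter baselines (variance, mean absolute
    difference, dispersion ratio, Spearman), a synthetic-data generator with
    known ground truth for end-to-end testing, and a benchmarking harness
    that aggregates trial results per transfer-function family.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
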