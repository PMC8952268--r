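Package: hrtbioind
Title: Bioindicator Discovery and Performance Prediction for Chain-Elongation Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step random-forest workflow for anaerobic bioreactor
    microbiomes: (1) identify amplicon sequence variants (ASVs) that act as
    bioindicators of hydraulic retention time (HRT) regimes via Gini-importance
    recursive feature elimination with cross-reactor validation, and (2)
    quantitatively predict chain-elongation process performance (n-caproate and
    n-caprylate productivities, concentrations and yields) from those
    bioindicators, with SMOTE class balancing, regression benchmarking and a
    replicate relative-RMSE evaluation protocol. Includes rarefaction and
    diversity statistics (Shannon, Bray-Curtis, NMDS, PERMANOVA with FDR
    control), Spearman co-occurrence network inference with Gephi-compatible
    export, and a synthetic two-reactor time-series generator with planted
    ground-truth bioindicators for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    randomForest,
    ranger,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse,
    biomformat
Config/testthat/edition: 3
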