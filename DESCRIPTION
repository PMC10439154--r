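Package: riverindic
Title: Bacterial Bioindicator Discovery Along River Continua
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies bacterial bioindicator taxa for biological status
    classification along longitudinally sampled river systems from 16S rRNA
    amplicon sequence variant (ASV) tables. Implements prevalence and
    coefficient-of-variation candidate screening, distance-based redundancy
    analysis with forward selection and collinearity filtering, beta-diversity
    threshold surfaces over an environmental gradient, a spatio-temporal ASV
    screening chain (random-forest prefilter, per-ASV window/lag grid search,
    greedy boosted-model building on an ordered upstream/downstream split, and
    a randomized screening ensemble), and co-occurrence/co-exclusion network
    analysis of the retained models. Ships a seeded synthetic river-microbiome
    generator with planted lagged indicators and known redundancy structure so
    the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    xgboost,
    randomForest,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat
Config/testthat/edition: 3
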