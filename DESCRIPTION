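Package: climNiche
Title: Ensemble Species Distribution Models and Climate-Niche Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds accuracy-gated ensembles of presence/absence species
    distribution models (generalized linear models, classification trees,
    random forests, small neural networks, generalized additive models and
    BIOCLIM-style surface range envelopes), evaluates members with the true
    skill statistic, and compares the predicted climate occupancy of
    population clusters via Schoener's D and Hellinger-based I niche-overlap
    statistics, permutation variable importance, and per-variable Wilcoxon
    rank-sum climate contrasts. Ships a synthetic-landscape generator with
    known ground-truth niches (spatially autocorrelated, cross-correlated
    climate fields; rejection-sampled presences and absences) so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    rpart,
    nnet,
    randomForest,
    mgcv
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
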