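Package: gxewindows
Title: Temporal Environmental Windows Behind Genotype-by-Environment
    Interaction in Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dissects genotype-by-environment (GxE) interaction in
    multi-environment trials by linking daily weather to trait variation.
    Derives thermal and photothermal indices (GDD, PTQ, PTT, DTR, PRDTR)
    from daily weather, decomposes phenotypic variance (fixed-effects
    ANOVA, Finlay-Wilkinson joint regression, GGE singular value
    decomposition), locates critical environmental time windows by an
    exhaustive sliding-window correlation scan and by random-forest
    feature importance with TreeSHAP attributions, and validates selected
    windows by leave-environments-out cross-validation. Includes a
    synthetic-data generator with known ground truth (planted critical
    windows, plasticity slopes) so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    ranger,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    e1071,
    glmnet,
    optparse
Config/testthat/edition: 3
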