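Package: gapred
Title: Genomics-Assisted Prediction for Fruit Texture Retainability
Version: 0.1.0
Authors@R:
    person("gapred", "maintainers", email = "gapred@example.org", role = c("aut", "cre"))
Description: Tools for QTL-marker based genomics-assisted prediction (GAP) of
    post-harvest flesh firmness and crispness retainability in bi-parental
    fruit-tree crosses. Converts monthly cold-storage firmness/crispness
    trajectories into integer retainability scores and softening-type classes,
    estimates per-marker genotype-class effects with dominance classification,
    pyramids effects into genomics-predicted values with repeated k-fold
    cross-validation, performs simulative truncation selection, and filters
    candidate genes within QTL intervals by variant impact, expression and
    differential-expression rules. A seeded F1-population simulator generates
    genotypes, true genetic values, phenotypes and storage trajectories so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
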