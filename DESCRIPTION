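Package: multipower
Title: Power and Sample-Size Design for Multi-Omic Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint statistical power and optimal sample-size calculation for
    multi-omic experiments combining normally distributed, count and binary
    data types. Significance levels are adjusted for false discovery rate
    control, power parameters can be estimated from pilot data through a
    pseudo-differential-feature percentile scheme, and the cost-minimal design
    is found for equal or unequal per-omic sample sizes by exact integer
    optimization. Includes a learning-curve module that predicts the sample
    size a multi-omic classifier (random forest or PLS-DA) needs to reach a
    target error rate, plus synthetic-data generators with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    glmnet,
    randomForest,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
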