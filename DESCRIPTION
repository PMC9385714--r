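Package: riboneutral
Title: Neutral Networks, In Silico Evolution, and Higher-Order Epistasis
    of Ligase Ribozymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring the empirical fitness landscape of a small
    RNA ligase ribozyme. Quantifies fraction-ligated and relative activity
    from barcoded deep-sequencing reads or pre-tabulated counts, designs
    ribozyme generations with in silico genetic operators (tournament
    selection, one-point crossover, point mutation), trains and evaluates
    neutral/deleterious sequence classifiers including a multilayer
    perceptron, runs a classifier-guided fully in silico evolutionary loop,
    and analyses epistasis with log-additive expectations, directional
    epistasis fits, reciprocal sign epistasis censuses, and the
    background-averaged Walsh-Hadamard decomposition of combinatorially
    complete landscapes, together with mutational-path accessibility
    analysis and synthetic-data generators for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    methods,
    minpack.lm,
    pROC,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
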