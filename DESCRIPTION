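Package: ciwo
Title: Chaotic Invasive Weed Optimization Feature Selection for
    Gene-Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional two-class
    gene-expression matrices using chaotic invasive weed optimization
    (IWO with logistic-map population initialization), coupled with a
    two-hidden-layer feedforward neural network trained by RMSprop.
    Includes a microarray-style preprocessing cascade (log transform,
    replicate collapsing, mean imputation, flat-pattern filtering,
    per-gene standardization), a synthetic two-class expression data
    generator with planted differentially expressed genes for offline
    validation, classification metrics with ROC/AUC, a repeated
    stratified hold-out evaluation protocol, and TSV/CSV/GCT input
    and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
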