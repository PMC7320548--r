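Package: igfresponse
Title: Transcriptional Response Analysis for IGF-1 Treatment in Patient-Derived Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq studies of IGF-1 treatment response in
    iPSC-derived neurons from ASD and neurotypical control individuals. Implements
    paired-design negative-binomial differential expression (TMM normalization,
    dispersion estimation, exact and GLM likelihood-ratio tests), permutation tests of
    transcriptional response magnitude, random-forest signature robustness checks,
    temporal signature grouping with aggregate trajectory tests, exact conditional
    odds-ratio overlap statistics, supervised co-expression modules with eigengene
    interaction models, projection of samples onto a control-derived principal-component
    response axis for responder stratification, and classification of treatment-driven
    recovery of baseline disease signatures. Includes a negative-binomial count
    simulator emulating the paired multi-arm study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
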