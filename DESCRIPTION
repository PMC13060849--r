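Package: surfkit
Title: Cell-Surface Proteome Analysis for MPNST Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for cell-surface-capture proteomics of
    malignant peripheral nerve sheath tumor (MPNST) models. Provides
    contaminant filtering and median normalization of label-free
    quantitation (LFQ) intensity matrices, consensus surfaceome selection
    across sample groups (detection-in-all, top-half-of-expression,
    surface-catalog intersection), PRC2-conditional differential surface
    abundance with cross-model intersection and hypergeometric
    over-representation analysis, RNA-protein concordance (global and
    decile-binned correlation, fold-change concordance, replicate
    correlation matrices), bead-calibrated surface antigen density
    quantification, four-parameter log-logistic dose-response
    fitting with IC50 extraction, and antigen-density/potency correlation.
    A synthetic-data generator with known ground truth makes every stage
    testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
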