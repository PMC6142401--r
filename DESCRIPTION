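Package: fcmodules
Title: Reproducible Functional Components from Expression Compendia by Multi-Run ICA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers reproducible transcriptomic modules ("functional
    components", FCs) from gene-expression compendia by SVD whitening,
    parallel-analysis component selection, multi-run independent component
    analysis and Hungarian-algorithm alignment of components across runs.
    Downstream tooling projects new studies into FC space, extracts
    active-gene modules with hypergeometric gene-set enrichment, tests FCs
    for differential expression, fingerprints tissues, and evaluates
    FC-space classifiers (one-vs-one SVM majority vote with call rates,
    McNemar comparisons, and a training-set subsampling harness). A
    synthetic-data module generates super-Gaussian source mixtures and
    two-class studies with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    limma,
    e1071,
    mgcv,
    fgsea,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'core-matrix.R'
    'compendium.R'
    'hungarian.R'
    'whiten.R'
    'ica.R'
    'consensus.R'
    'fcspace.R'
    'evaluate.R'
    'fcmodules-package.R'
    'pipeline.R'
    'synthdata.R'
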