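Package: spliceSRE
Title: Biophysical Modeling and Sparse Inference of Splicing Regulatory
    Elements from Cassette-Exon Inclusion Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies hexamer splicing regulatory elements (SREs) and
    cooperative SRE pairs from cassette-exon inclusion profiles measured
    across tissues. A thermodynamic occupancy model of spliceosome and
    splicing-factor binding yields a linear model on the logit of the exon
    inclusion ratio; the model is fit by a four-stage high-dimensional
    inference framework (marginal and interaction screening with
    hypergeometric co-occurrence tests, Lasso and adaptive Lasso with
    cross-validated penalties, refitted cross-validation variance
    estimation, and OLS refitting with Benjamini-Hochberg FDR control).
    Includes cassette-exon selection from genePred annotation, extraction
    of the five masked sequence regions around each exon, effect-sign
    classification from splicing-factor expression, a forward simulator
    with known ground truth, and a motif-list overlap-enrichment utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'spliceSRE-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'genepred.R'
    'ase-selection.R'
    'biophysics.R'
    'features.R'
    'penalized.R'
    'response.R'
    'regions.R'
    'selection.R'
    'screening.R'
    'pipeline.R'
    'simulate.R'
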