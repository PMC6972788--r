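Package: ukaKinome
Title: Upstream Kinase Activity Inference from Peptide Microarray Kinome Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers differential upstream kinase activity between two groups
    of samples from peptide-microarray phosphorylation profiles (tyrosine and
    serine/threonine kinome chips). Provides multi-exposure signal
    integration, log transformation, run-date batch centering and quality
    control; rank-weighted kinase-substrate mapping scanned over evidence-rank
    cutoffs; and a kinase ranking built from a normalized median kinase
    statistic, a random-peptide-set specificity score and a label-permutation
    significance score. Includes a synthetic-data generator with planted
    kinase effects for end-to-end validation, and exporters for final-score
    plot data and kinome-tree annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
biocViews: Proteomics, Phosphoproteomics, Normalization,
    QualityControl, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'io.R'
    'methods-accessors.R'
    'peptide-id.R'
    'preprocess.R'
    'report.R'
    'scoring.R'
    'simulate.R'
    'substrate-map.R'
    'ukaKinome-package.R'
    'utils.R'
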