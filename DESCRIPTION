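Package: perinatomics
Title: Multi-Omics Differential Abundance and Network Analysis for
    Diabetic-Pregnancy Offspring Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for liver multi-omics studies of
    offspring exposed to maternal hyperglycemia. Provides lipidomics
    quality control with QC-pool coefficient-of-variation and
    dispersion-ratio (D-ratio) filtering followed by k-nearest-neighbour
    imputation; post-quantification processing of DIA precursor reports
    (q-value filtering, charge-state aggregation, MaxLFQ protein
    quantification, detection filtering and iterative imputation);
    feature-wise two-way ANOVA with pooled Benjamini-Hochberg correction,
    Tukey HSD follow-up and fold-change based significance calls;
    multivariate statistics (PCA, Ward clustering, OPLS-DA with
    leave-one-out cross-validation, permutation testing and VIP scores,
    co-inertia analysis with the RV coefficient); protein-protein
    interaction network statistics (largest-connected-component
    significance, random walk with restart expansion, disease Jaccard and
    network proximity screening, gene-set over-representation); and a
    synthetic-data generator that plants known effects so every stage of
    the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
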