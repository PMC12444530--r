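Package: qsprgraph
Title: Topological-Index QSPR Models for Standard Combustion Enthalpy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds explicit-hydrogen molecular graphs from SMILES strings,
    computes spectral and distance-based topological indices (Estrada,
    Wiener, Gutman) together with node-centrality statistics, and fits
    quantitative structure-property relationship (QSPR) models for the
    standard combustion enthalpy of organic compounds.  Includes ordinary,
    ridge and Huber linear regression, CART / random-forest /
    extremely-randomized-trees ensembles with impurity importances,
    Monte-Carlo Shapley attribution, model-selection protocols (hold-out,
    k-fold and nested cross-validation, random hyperparameter search,
    learning curves), and clustering of the topological chemical space
    (k-means++ with elbow scan, DBSCAN, silhouette and Davies-Bouldin
    validity).  A homologous-series generator provides reproducible
    fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    MASS,
    cluster,
    rpart,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
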