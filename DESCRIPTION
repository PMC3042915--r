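Package: kdeCluster
Title: Nonparametric Density-Based Clustering of Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised clustering of samples in high-dimensional
    expression matrices via a three-step procedure: univariate
    density-based gene filtering, principal-component dimensionality
    reduction, and nonparametric level-set clustering of the reduced
    scores. Clusters are the connected components of high-density
    regions of a Gaussian product-kernel density estimate, linked
    through a Delaunay neighbour graph, so the number of clusters is
    detected from the data rather than pre-specified. Includes two
    hierarchical expression simulators (Gamma-Gamma and
    Normal-Uniform) with full ground truth, the matching evaluation
    metrics (error rate, sensitivity, specificity, cluster-count and
    gene-selection error), and readers plus standard microarray
    preprocessing recipes (thresholding, intensity filters, log
    transform, quantile normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    limma,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Clustering, GeneExpression, Microarray, DimensionReduction
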