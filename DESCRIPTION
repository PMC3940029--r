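Package: pfclust
Title: Parameter-Free Clustering of Similarity Matrices
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitioning of a pairwise similarity matrix into an
    automatically determined number of clusters. Candidate admission
    thresholds are estimated from the upper tail of intra-cluster
    similarities observed under repeated random partitioning of the data;
    for each threshold an agglomerative engine builds clusters whose mean
    intra-cluster similarity stays above the threshold, and the silhouette
    width selects the clustering that best describes the data. Includes
    readers and writers for delimited similarity matrices and point
    tables, similarity kernels for feature-vector input, a synthetic
    benchmark generator with known ground truth (Gaussian blobs, rings,
    elongated and mixed-density clusters), the Rand index for comparing
    partitions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
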