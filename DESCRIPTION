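Package: icclust
Title: Hybrid Genetic Clustering of EEG Independent Component Topographies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clustering of independent component (IC) scalp topographies
    from multi-subject EEG recordings, using the absolute Pearson
    correlation between ICA inverse-weight columns as the similarity
    measure. Implements spectral pre-clustering on the symmetric
    normalized Laplacian of the similarity graph, an elitist clustering
    genetic algorithm with merge/agglomerative/split/move mutations that
    adapts the number of clusters and an outlier pool, a polarity-inversion
    solver (exhaustive and genetic) that resolves the ICA sign ambiguity
    before averaging cluster centroids, and correlation-adapted cluster
    validity indices (quality index, local-density quality index,
    silhouette, inverted Davies-Bouldin, and an eye-label concordance
    score). A synthetic scalp-map generator with planted clusters,
    polarity flips, noise and outliers supports testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml
Config/testthat/edition: 3
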