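Package: rootart
Title: Algorithmic Root Traits from Segmented Root Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts Algorithmic Root Traits (ARTs) from binary segmented
    root images: an ensemble of nine clustering procedures (DBSCAN, HDBSCAN,
    OPTICS, mean-shift, Gaussian mixtures, K-means, fuzzy C-means, SLIC
    superpixels and a kernel-density-guided custom procedure) each locates
    the largest dense root cluster in a mask and reports its pixel count and
    centroid, yielding a 27-column trait table. Also provides the downstream
    drought-phenotyping toolkit built on those traits: feature-set
    comparison (internal variability, PERMANOVA, ordination, cluster
    separation indices), robust genotype ranking (trimmed-mean stress
    metrics, weighted rank scores, Cliff's delta, normality-gated test
    batteries, genotype clustering with internal and external validation),
    and a bootstrap-plus-noise augmented random-forest classification
    framework with permutation importance, algorithm ablation and an
    information-density summary. Ground-truthed synthetic mask and feature
    generators make every stage testable without real images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    pROC,
    png,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
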