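Package: dendrosnip
Title: Guided Piecewise Snipping of Hierarchical Clustering Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes a hierarchical-clustering tree of patient molecular
    profiles into non-overlapping clusters by snipping branches at variable
    heights. The complete set of tree-consistent partitions is enumerated
    under a minimum-cluster-size constraint and each candidate is scored
    both by a molecular cluster-quality measure (within-cluster sum of
    squares, Hubert-Levin C-index or Goodman-Kruskal index) and, when
    censored time-to-event follow-up is available, by an information
    criterion of a Cox proportional-hazards fit on the cluster labels; the
    two scores are combined by rank summation to pick the optimal partition.
    Also provides fixed-height cutting for comparison, test-sample
    assignment by Ward increment or by pseudo-nearest-neighbour concordance,
    cross-validated log-rank validation, and a Gaussian-mixture simulation
    harness with cluster-linked exponential survival.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, survival, jsonlite, MASS
Suggests: testthat (>= 3.0.0), mclust, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
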