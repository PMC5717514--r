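Package: honmst
Title: High-Order Network Minimum-Spanning-Tree Classification of Dynamic
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds dynamic (sliding-window) functional connectivity
    networks from regional fMRI time series, derives high-order networks
    by correlating the connectivity time series of region pairs, prunes
    them to minimum spanning trees (Kruskal or Prim), extracts weighted
    clustering-coefficient features, and classifies two subject groups
    with Relief feature weighting, pairwise redundancy pruning, and a
    nested multi-parameter RBF-SVM cross-validation framework.  Includes
    a synthetic-cohort generator that plants group differences in the
    temporal co-fluctuation of region-pair connectivities, static Pearson
    and partial-correlation baselines, and reporting aggregations of
    feature weights at the region and lobe-module level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
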