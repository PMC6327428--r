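Package: acolink
Title: Ant-Colony-Clustering-Based Bipartite Network Prediction of
    lncRNA-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts unobserved lncRNA-protein interactions from a binary
    bipartite interaction network. Long non-coding RNA association profiles
    are clustered with an ant-colony algorithm driven by pheromone dynamics
    and refined by a mutation step; a linear neighborhood similarity matrix
    over the profiles is enhanced with the recovered cluster structure; and
    interaction scores are obtained by label propagation on the bipartite
    network, with an exact linear-solve fixed point available as a check.
    Includes random walk with restart and two-phase resource-allocation
    baselines, a repeated k-fold edge-masking cross-validation harness with
    rank-based and thresholded metrics, and generators for synthetic
    block-structured networks and Gaussian point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
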