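Package: amfes
Title: Adaptive SVM-Based Gene Selection, Kernel Mutual-Information
    Matrices and Target-Network Synergy Scoring
Version: 0.3.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks and selects class-informative genes from labeled
    expression matrices by an adaptive support-vector-machine scheme:
    genes are scored by the drop in the SVM dual objective when their
    coordinate is removed from the support vectors, ranked by recursive
    halving with randomized half-size gene subsets, and thresholded
    against randomly permuted probe genes on a validation-accuracy grid.
    Also estimates pairwise gene-gene mutual information with Gaussian
    kernel densities (loop-nest-optimized matrix form plus condition
    contrast statistics) and scores the synergy of agent gene-set pairs
    on a background interaction network via centrality-based node
    importance, topology score, agent score and their product.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
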