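Package: netskeleton
Title: Network Skeleton Extraction for Gene Co-Expression Graphs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic spectral sparsification of gene co-expression
    networks. Builds complete |correlation|-weighted graphs over gene sets,
    ranks edges by effective-resistance importance, removes the least
    important edge iteratively with full recomputation, and stops at the
    elbow of the median prediction mean-squared-error curve while keeping
    the graph connected. Includes probabilistic (importance-sampled)
    sparsification for spectrally-matched null models, skeleton comparison
    statistics (normalized Hamming distance, Jaccard index, spectral
    distance) with permutation p-values, a synthetic block-correlated
    expression generator, replicate-subsampling reproducibility
    experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
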