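Package: succ
Title: Microbial Succession Under Heavy-Metal Stress: Pollution Indices,
    Co-Occurrence Networks, and Community Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for characterising microbial community
    succession along heavy-metal pollution gradients, as in mine-tailings
    primary succession studies.  Computes soil heavy-metal pollution indices
    (geo-accumulation index, single pollution index, Nemerow integrated
    pollution index), alpha diversity and permutation statistics (Mantel,
    partial Mantel, PERMANOVA), thresholded Pearson co-occurrence networks
    with a full topological metric suite, cohesion, Louvain modules and a
    composite network-complexity score, and phylogenetic null-model
    partitioning of community assembly into deterministic and stochastic
    processes via abundance-weighted betaMNTD/betaNTI and the Bray-Curtis
    Raup-Crick index.  Includes a synthetic-community generator with known
    assembly regimes (environmental filtering, neutral, dispersal-limited)
    so every stage can be exercised against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    biomformat,
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
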