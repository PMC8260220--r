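Package: covchange
Title: Coordinated Longitudinal Volumetric Change: Clustering, Null
    Models, and Twin Genetic Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing coordinated longitudinal change in regional
    brain volumes. Computes annualized symmetrized percent change (APC) per
    subject and region, builds change-change correlation matrices across
    subjects, and decomposes them into clusters with a signed Louvain
    modularity algorithm, including modal and consensus partitions and
    versatility-guided resolution selection. Significance is assessed against
    degree-preserving signed rewired networks, and matrices and partitions are
    compared with Mantel permutation tests and partition-similarity statistics
    (normalized mutual information, variation of information, z-scored Rand
    coefficient). A bivariate latent change score ACE twin model estimates
    genetic correlations of volumetric change between regions. A synthetic-data
    module generates longitudinal cohorts with planted cluster structure and
    MZ/DZ twin samples with known ACE components so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan,
    withr
Config/testthat/edition: 3
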