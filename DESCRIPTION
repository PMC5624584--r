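Package: gtamarkers
Title: Game-Theoretic Identification of Discriminative Subnetwork Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies discriminative subnetwork markers from a
    protein-protein interaction network and a two-phenotype gene
    expression profile.  Each gene is scored by the Welch t-statistic of
    its per-sample log-likelihood ratio under Gaussian class densities;
    candidate subnetworks are grown two steps around high-scoring seeds,
    pruned by the seed's local clustering coefficient, decomposed into
    per-anchor sub-games, and solved by exhaustive pure-strategy Nash
    equilibrium search over a payoff combining expression evidence,
    neighbourhood support, subnetwork density and a size penalty.
    Includes a synthetic-data generator with a planted dense
    differentially expressed module for benchmarking, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
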