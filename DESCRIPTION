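Package: pvrpart
Title: Partitioning Trait Variance into Phylogenetic, Environmental, and
    Intraspecific Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how plant evolutionary history, climate, soil, and
    intraspecific variation jointly explain variation in a continuous
    functional trait such as specific leaf area (SLA). Provides phylogenetic
    signal statistics (Moran's I, Abouheif's C_mean, Blomberg's K, Pagel's
    lambda) with permutation tests, phylogenetic eigenvector regression with
    commonality analysis of R-squared across phylogenetic, climatic, and soil
    predictor classes, a residual-based estimate of the intraspecific
    contribution, nested random-effects variance decomposition,
    single-predictor mixed-model environment screens with AIC-based
    linear/quadratic selection, and node-by-node divergence contribution
    indices along a phylogeny. A synthetic-data generator produces trees,
    traits, and site environments with known ground-truth variance fractions
    so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
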