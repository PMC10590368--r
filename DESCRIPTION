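Package: zoonet
Title: Signed Co-Occurrence Network Analysis for Zooplankton Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares signed, weighted co-occurrence networks from
    taxon-by-sample biomass tables. Taxon biomasses are autoscaled, pairwise
    correlations are thresholded at the critical value for the class sample
    size, and the resulting undirected graphs carry correlation sign and
    absolute-correlation edge weights. Provides the global network attributes
    (clustering coefficient, centralization, density, heterogeneity,
    characteristic path length, shortest-path coverage, mean neighbourhood
    size) and node centralities (degree, closeness, betweenness, local
    clustering) used to rank taxa, community diversity statistics (Shannon,
    Pielou, Jaccard) with ANOVA/Tukey and Kruskal-Wallis class comparisons,
    gradient-boosted feature-importance ranking of environmental variables,
    and a latent-factor lognormal community simulator with known guild and
    antagonist structure for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
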