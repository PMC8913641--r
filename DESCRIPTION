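Package: zoonet
Title: Turbidity-Stratified Zooplankton Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers significance-thresholded signed Pearson correlation
    networks from zooplankton community biomass tables partitioned by water
    turbidity class (high, moderate, low), and compares the resulting
    communities through NetworkAnalyzer-compatible global network attributes
    (clustering coefficient, centralization, density, heterogeneity,
    characteristic path length), node and edge centralities (degree,
    closeness, betweenness, edge betweenness), divisive edge-betweenness
    clustering, and community diversity statistics (Shannon H', Pielou J',
    ANOVA with Tukey groups, Kruskal-Wallis). Includes a seeded
    Gaussian-copula generator of community biomass data with planted guild
    and predator-prey correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    multcomp,
    stats,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
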