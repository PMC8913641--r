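# zoonet

Turbidity-stratified co-occurrence network analysis for zooplankton
communities.

## The problem

Water turbidity reshapes who co-occurs with whom in reservoir
zooplankton. Given wide biomass tables (sampling events × taxa, mg/l)
partitioned into high- (> 25 NTU), moderate- (15–25 NTU) and
low-turbidity (< 15 NTU) classes, zoonet infers one signed
co-occurrence network per class and computes the whole-network
attributes and node/edge centralities used to compare community
structure along the gradient. It is aimed at plankton and community
ecologists who want this style of analysis scripted, seeded and tested
instead of assembled by hand across GUI tools.

## The method

Within each class, taxa are autoscaled (per-column z-scores) and every
taxon pair is scored by Pearson correlation over pairwise-complete
observations. A pair (i, j) becomes an edge exactly when

    |r_ij| >= r_crit(n, alpha),   r_crit = t / sqrt(t^2 + n - 2),

where `t` is the two-sided t quantile at `n − 2` df — i.e. the edge set
is the set of correlations significant at P ≤ alpha for the class
sample size (alpha = 0.05 by default; Benjamini–Hochberg correction
optional). Edges carry r, its sign (positive: guild coexistence;
negative: predation/competition) and weight |r|.

Each network is summarized by NetworkAnalyzer-compatible metrics:
clustering coefficient, degree centralization `(n/(n−2))(k_max/(n−1) −
density)`, ordered connected-pair ("shortest paths") count,
characteristic path length, mean neighbors `2E/n`, density
`2E/(n(n−1))`, degree heterogeneity (CV of degrees), node degree /
closeness / betweenness centralities (NDC, NCC, NBC) and unnormalized
edge betweenness (EBC), plus divisive edge-betweenness (Girvan–Newman)
sub-network detection. Per-sample Shannon H′ and Pielou J′ and
ANOVA/Tukey or Kruskal–Wallis class comparisons round out the report.

A seeded Gaussian-copula generator (`make_study_fixture()`) produces
three class datasets (158×27, 180×28, 136×22) with planted guild and
antagonist correlation structure, so the full pipeline is testable
end to end. See `vignettes/turbidity-networks.Rmd` for the model,
conventions and design choices.

## A worked example

```r
library(zoonet)
cfg <- run_config(synthetic = TRUE, seed = 1, outdir = "zoonet_out")
report <- run_turbidity_pipeline(cfg)
report$class_attributes[, c("class", "n_nodes", "n_edges", "density",
                            "mean_neighbors", "clustering_coefficient",
                            "characteristic_path_length", "heterogeneity")]
#>  class n_nodes n_edges density mean_neighbors clustering_coefficient
#>     HT      27     104  0.2963          7.704                 0.6591
#>     MT      28      65  0.1720          4.643                 0.3959
#>     LT      22      51  0.2208          4.636                 0.5061
#>  characteristic_path_length heterogeneity
#>                       2.026        0.3547
#>                       2.125        0.6816
#>                       2.300        0.4933
```

The high-turbidity network is the densest and most clustered (each
taxon interacts with ~7.7 others on average), the moderate class the
sparsest, with density = mean_neighbors/(n−1) holding in every row.
Class diversity differs sharply:

```r
report$comparisons$shannon_h
#> <comparison_result> shannon_h: anova statistic = 89.59, df = 2, 471, p = 1.066e-33
#>   Tukey groups: HT=a, LT=b, MT=a
```

and the taxa bridging sub-networks stand out by betweenness:

```r
nc <- report$centralities$HT
head(nc[order(-nc$nbc), ], 3)
#>     taxon ndc   ncc    nbc isolated
#>  taxon_12  13 0.605 0.1796    FALSE
#>  taxon_14  10 0.542 0.1056    FALSE
#>  taxon_18   8 0.565 0.0918    FALSE
```

The significance threshold itself is a one-liner: at the HT sample size,
`critical_r(158, 0.05)` is `0.1562`, so any |r| ≥ 0.156 becomes an edge.

All per-class edge lists, GraphML/SIF exports, attribute, centrality and
diversity tables, and a JSON manifest of the configuration and every
data-cleaning action land in `outdir`. A thin CLI wraps the same
functions: `Rscript inst/cli/zoonet.R run-all --seed 1 --outdir out/`.

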