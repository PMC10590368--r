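# zoonet

Signed co-occurrence network analysis for zooplankton (and other taxon
biomass) communities.

Community ecologists increasingly read the *structure* of pairwise biomass
correlations as a fingerprint of biocoenosis organisation: positive
correlations mark co-occurrence within consumption guilds, negative ones mark
predation or competition, and whole-network attributes (cohesion, centrality,
path structure) summarise how tightly the community is organised — for
example when comparing water bodies across a thermal gradient. `zoonet`
implements that workflow end to end for anyone with a samples × taxa biomass
table: limnologists comparing reservoirs or lakes, and methodologists who
need a calibrated simulator to study how well such networks recover known
interactions.

## The method

Given a biomass matrix **B** (samples × taxa) for one class of samples:

1. **Autoscaling.** Each taxon column is standardized,
   *z* = (*x* − x̄)/*s*; constant taxa are excluded and listed.
2. **Correlation.** The full Pearson (or Spearman) correlation matrix
   **R** is computed on the autoscaled data.
3. **Edge significance.** A taxon pair becomes an undirected edge iff
   |*r*| ≥ *r*\*(*n*, α), where

   *r*\* = *t*\* / √(df + *t*\*²),  df = *n* − 2,

   and *t*\* is the two-sided Student-*t* quantile at level α (default
   0.05). For *n* = 84 samples, *r*\* ≈ 0.2146. Edges carry the sign of *r*
   and the weight |*r*|.
4. **Network attributes.** Per network: mean local clustering coefficient,
   degree centralization *C* = (*n*/(*n*−2))·(*k*max/(*n*−1) − density),
   density 2*m*/(*n*(*n*−1)), heterogeneity CV(*k*), characteristic path
   length, and the count/coverage of shortest paths over ordered reachable
   pairs. Per taxon: degree (NDC), closeness (NCC = 1/mean distance to
   reachable taxa), betweenness (NBC, component-normalized) and local
   clustering (CCF = 2*e*\_N/(*k*(*k*−1))). Path metrics default to hop
   counts; a weighted mode sums |*r*| as edge length.
5. **Community statistics.** Shannon *H*′ = −Σ *p*ᵢ ln *p*ᵢ, Pielou
   *J*′ = *H*′/ln *S*, Jaccard similarity *P*′ = 100·|A∩B|/|A∪B| between
   class taxon lists, one-way ANOVA + Tukey HSD and Kruskal–Wallis class
   comparisons, Spearman rank correlations.
6. **Environmental discrimination.** Gradient-boosted trees (xgboost,
   softmax) rank physico-chemical variables by split-frequency importance
   ("F score") for separating the classes, with a stratified train/test
   split; a deterministic one-way-ANOVA-F mode is included.

A latent-factor lognormal **simulator** generates multi-class communities
with known guild (positive) and antagonist (negative) interaction ground
truth, plus seasonal temperature forcing and correlated hydrochemistry, so
recovery, calibration and power can be measured against a known answer.

## Worked example

```r
library(zoonet)

scenario <- generate_scenario(scenario_config(rng_seed = 1))
classes  <- split_by_class(scenario$community)
net_cw   <- infer_network(classes$CW, zoonet_config(alpha = 0.05))
net_cw
#> interaction_network: 61 taxa, 309 edges (152 positive, 157 negative)
#> n = 84, alpha = 0.05, |r| threshold = 0.2146

global_attributes(net_cw)
#> nodes 57 (isolated excluded: 4), edges 309
#>   Clustering coefficient       0.5627
#>   Network centralization       0.188
#>   Shortest paths               3192
#>   Shortest paths (%)           100
#>   Characteristic path length   2.283
#>   Average number of neighbors  10.84
#>   Network density              0.1936
#>   Network heterogeneity        0.5614

head(node_table(net_cw, sort_by = "NDC"), 3)
#>         taxon NDC       NCC        NBC       CCF
#> 1     CW_T013  21 0.5656566 0.07087921 0.5000000
#> 2 Shared_T018  21 0.5185185 0.04406212 0.5095238
#> 3     CW_T002  19 0.5333333 0.09863029 0.4853801

round(jaccard_matrix(scenario$community), 1)
#>       CW    MW    WW
#> CW 100.0  39.2  33.9
#> MW  39.2 100.0  30.4
#> WW  33.9  30.4 100.0
```

Reading the output: of 61 simulated cold-winter taxa, 57 enter the network
(4 carry no significant correlation), joined by 309 edges with a near-even
positive/negative split. The network is fully connected (100% shortest-path
coverage), moderately dense (0.19) and strongly clustered (0.56) — the
cohesive regime the cold-winter guild structure was configured to produce.
The node table ranks hub taxa by their number of significant partners, and
the Jaccard matrix quantifies how much the three class taxon lists overlap
(about a quarter of the union is common to all three).

`run_pipeline()` performs all of the above per class and across classes in
one call and `write_report()` / `write_summary_tables()` /
`write_network()` export JSON, Table-shaped TSVs and
Cytoscape-compatible GraphML/SIF. A thin command-line wrapper lives at
`inst/cli/zoonet.R` (`simulate`, `analyze`, `compare` subcommands).

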