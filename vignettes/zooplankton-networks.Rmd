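---
title: "Methods: signed co-occurrence networks from taxon biomass tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed co-occurrence networks from taxon biomass tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoonet)
```

## The inference model

`zoonet` treats a community of taxa sampled repeatedly under one regime (a
"class") as a multivariate sample of biomasses and asks which taxon pairs
co-vary beyond what sampling noise explains. The procedure is deliberately
plain: autoscale each taxon (zero mean, unit sample SD), compute the full
pairwise Pearson correlation matrix, and keep as edges exactly the pairs
whose |r| reaches the two-sided critical value for the class sample size,

$$ r^*(n, \alpha) = \frac{t^*}{\sqrt{n - 2 + t^{*2}}}, \qquad
   t^* = t_{1-\alpha/2,\,n-2} . $$

This threshold formulation is mathematically identical to testing each
pair's r at level $\alpha$ under bivariate normality, and it makes the edge
rule auditable: one number per network (`r_critical`, reported in every
object) separates edge from non-edge. Ties at the threshold are included
($P \le \alpha$ is inclusive). No multiple-testing correction is applied by
default — the analysis this package standardises uses the plain per-pair
rule — but the machinery is exposed so users can filter edges themselves
from the exported correlation table.

Assumptions worth stating. Pearson r on (autoscaled) biomass responds to the
marginal distributions: biomass is typically lognormal-ish, so correlations
on the raw scale are attenuated relative to the log scale (see the simulator
section — this is why recovery tolerances are wider than Fisher-z theory for
normal data would suggest). Spearman correlation is available
(`correlation_method = "spearman"`) when monotone-but-nonlinear association
is the better model. Edges are correlational: "positive = guild,
negative = predation/competition" is an ecological reading, not something
the mathematics can certify.

## Network attributes and their conventions

Topology metrics follow the conventions of the NetworkAnalyzer family of
tools, which matters because several quantities have competing definitions:

* **Local clustering (CCF)** is $2e_N/(k(k-1))$ and **defined as 0 for
  degree < 2**; these zeros are included in the network mean.
* **Closeness (NCC)** is the reciprocal of the *mean* shortest-path distance
  to reachable nodes only; isolated nodes get 0. On a connected unweighted
  network this lies in (0, 1].
* **Betweenness (NBC)** is normalized by the pair count of the node's own
  connected component, $(n_c-1)(n_c-2)/2$; for connected networks this
  equals whole-graph normalization, and it keeps values in [0, 1] when a
  network fragments.
* **Centralization** is the degree-based index
  $(n/(n-2))(k_{max}/(n-1) - \text{density})$: 1 for a star, 0 for any
  vertex-transitive graph.
* **Heterogeneity** is the coefficient of variation of the degree sequence
  with the population variance.
* **Shortest paths** are counted over *ordered* reachable pairs, so a
  connected n-node network reports $n(n-1)$ paths and 100% coverage.
* **Path lengths** default to hop counts (`path_metric_mode =
  "topological"`). A weighted mode treats |r| as additive edge length; it is
  provided because the alternative reading (distance = sum of weights) is
  also defensible, but hop counts are the default since they reproduce the
  integer shortest-path counts practitioners know from the desktop tools.
* **Isolated nodes** are excluded from global metrics by default
  (`include_isolated = FALSE`): a taxon with no significant correlation
  carries no interaction information, and keeping it would deflate density,
  clustering and coverage in a way that depends on how many rare taxa were
  recorded rather than on interaction structure. The exclusion count is
  always reported, the full node list stays in `node_table()`, and the
  switch is exposed.

Every one of these choices is pinned by tests against an independent
brute-force oracle that enumerates all simple paths on small graphs, plus
closed-form checks (complete graphs, stars, paths, rings) asserted exactly.

## Diversity and class comparison

Shannon diversity uses natural logarithms by default (nats), configurable to
base 2 or 10; the choice is recorded in reports. $H'$ and $J'$ are computed
per sample and summarised as class mean ± SD (the presentation used in
field studies), with pooled-community values also reported, because surveys
rarely state which of the two conventions they used. Diversity is computed
on whatever the matrix holds — biomass shares by construction here;
abundance tables work identically. Jaccard similarity is reported as a
percentage of the shared taxon union; two empty sets are defined as 100%
similar, with a warning.

Class comparisons: one-way ANOVA with Tukey's HSD (homogeneous-subset
letters assigned only when the omnibus p ≤ α; groups sharing a letter never
differ at level α in the pairwise tests — property-tested), and the
tie-corrected Kruskal–Wallis test for biomass-like quantities with many
tied zeros. The degenerate all-constant, all-equal case reports p = 1 rather
than NaN.

## The synthetic community generator

The study setting this package targets has non-public raw data, so the
generator is a first-class module, not a test fixture. It emulates the
statistical setting the inference assumes:

$$ \log B_{js} = \mu_j + \sum_g L_{jg} F_{gs} + w_j T_s + \varepsilon_{js},
   \qquad F_{gs} \sim N(0,1),\ \varepsilon_{js} \sim N(0, \sigma^2), $$

with taxa partitioned into consumption guilds (loading $+a$ on their guild
factor), a configurable fraction of antagonists per guild (loading $-a'$),
optional "bridge" taxa loading on a second guild factor (the
subnetwork-connector motif), optional per-taxon loading jitter, and biomass
$B = \exp(\log B)$ rescaled so the sample-mean total biomass matches the
class target exactly. The log-scale population correlation is closed-form,
$\mathrm{cov2cor}(LL^\top + \sigma^2 I)$ — for two taxa sharing one factor,
$a_i a_j / \sqrt{(a_i^2+\sigma^2)(a_j^2+\sigma^2)}$ — and is returned as
ground truth with every generated matrix. That closed form is the oracle the
recovery tests use.

Default scenario (three classes × 84 samples): taxon counts 61/74/89, mean
total biomass 28.25/0.730/0.094 mg l⁻¹, winter temperature 5.63 ± 2.19 /
8.60 ± 0.76 / 15.35 ± 1.41 °C, annual means 13.61/14.69/18.49 °C, and
per-class hydrochemical profiles, all taken from the per-class summary
statistics of the reservoir system the package emulates. Guild structure
decreases in cohesion from the cold class (3 guilds, 60% of taxa structured,
half of each guild antagonists) to the warm class (8 guilds, 40% coverage,
15% antagonists). Loadings default to $a = a' = \sigma = 0.35$: the equality
pins every ground-truth pair at |population r| = 0.5 on the log scale (the
calibration point for recovery studies), and the absolute scale — per-taxon
log-SD $\sqrt{2}\cdot 0.35 \approx 0.5$, i.e. about 1.6× multiplicative
variation per SD — was chosen once as a realistic whole-season
within-taxon variation for a model that deliberately excludes seasonal
biomass dynamics. Per-taxon baselines $\mu_j \sim N(0, 1.25)$ give a
lognormal rank-abundance spread. About 26% of the taxon union is shared by
all classes by default (`shared_fraction`), mirroring the overlap a
multi-reservoir survey reports; shared taxa keep their identity across
classes but draw guild roles independently.

The environment generator emulates a monthly campaign in which hydrochemistry
is measured once per reservoir per date, so station replicates share one
row. Temperature follows an annual cosine with its trough in mid-January;
the amplitude is set so the December–February mean equals the configured
winter mean (that is what a "winter temperature" summary statistic reports)
and the level so the annual mean matches, plus per-date noise. Dissolved
oxygen couples negatively to temperature (Gaussian coupling −0.52, giving
Spearman ≈ −0.5). The remaining variables keep their configured means/SDs
but are drawn with two shared within-date axes — suspended matter
(turbidity, colour, SS fractions, iron, with transparency loading
negatively) and trophic state (chlorophyll, organic carbon, N and P) — and a
fixed class-common seasonal component with textbook signs (production and
suspension peak in summer, transparency and nitrate in winter). Physically
non-negative variables are truncated at zero.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: temporal autocorrelation and seasonal succession
in biomass (the model is exchangeable across samples by design; per-taxon
thermal sensitivity exists but defaults to off so network tests are not
confounded by shared trends), zero inflation (every present taxon has
positive biomass in every sample; real tables are mostly zeros for rare
taxa), compositional constraints, interannual effects, and any
distributional feature of the environmental data beyond means, SDs, the
stated correlation structure and the annual cycle. The last limitation is
consequential: per-sample class discrimination on the synthetic environment
is substantially easier than on the real measurements the emulated study
reports, and the variable ranked most important by boosted trees on
synthetic data is typically the cleanest marginal separator (Secchi
transparency) rather than temperature, whose class-conditional annual
distributions overlap heavily. The discrimination module is therefore
validated on constructed separable fixtures (a variable known to carry the
class signal must rank first in both boosted and ANOVA-F modes, and must
lose its rank under label permutation) rather than on a reproduction of the
original study's importance ordering.

## Structured presets

`cw_like_preset()` and `ww_like_preset()` encode the two cohesion regimes
used in power studies: few large guilds with strong, taxon-varying loadings,
balanced antagonists and a small share of strong two-guild generalists
(hub taxa) versus many small guilds with marginal loadings, few antagonists
and weak bridge chaining. The generalist taxa matter: two uniform cliques
have near-zero degree centralization no matter how strong their loadings, so
a cohesive-and-centralized network needs taxa whose interactions span
guilds — which is also the ecological picture of broad-diet consumers. The
acceptance suite checks that the cohesive preset beats the weak preset on
clustering and centralization and has shorter characteristic path length in
at least 90% of 50 paired runs.

## Numerical and reproducibility choices

* Autoscaling uses the sample (n−1) SD; Pearson r is scale-invariant, so
  this affects only reported z-scores, never edges.
* Correlation matrices are symmetrized exactly ((R + Rᵀ)/2, unit diagonal)
  so thresholding can never produce an asymmetric edge set.
* Edge tables and node tables are ordered by taxon name; all ties break
  lexicographically, making every export byte-stable.
* One master seed drives a scenario; per-class streams are derived by a
  stable hash of the class name, so results are identical regardless of
  class order and remain below the 32-bit integer limit.
* The boosted mode demands a seed and records the stratified split in the
  report (default 2/3 train); its importance measure is split frequency
  ("F score"), with gain available.
* Degenerate inputs have defined behaviour rather than errors where a
  defined value exists: constant taxa are excluded and listed, richness-1
  evenness is NA with a warning, edgeless networks report NA path metrics,
  and classes with fewer than 4 samples are rejected because the edge rule
  is undefined below df = 2.
* Problem sizes in the test and acceptance suites (500 oracle graphs of 4–7
  nodes, 10⁵ permutation draws, 200 recovery replicates, 50 preset pairs,
  2000 null comparisons) were chosen so each check's Monte-Carlo error is
  small against its tolerance while the whole suite stays fast enough to run
  routinely.

## Known limitations

Plain correlations on autoscaled biomass are the method being packaged, not
a recommendation against compositional or conditional-dependence methods;
no SparCC-style correction is included by design. The node-inclusion rule
that real studies apply before reporting network sizes is often unstated, so
the prevalence filter defaults to off and isolated-node handling is a
documented switch rather than a guess. Weighted betweenness is available but
the weighted mode's oracle coverage extends only to distances and closeness;
topological mode is the validated default.
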