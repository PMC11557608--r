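# UPRnet

Statistical-mechanics characterization of protein–protein interaction (PPI)
networks, built around the unfolded protein response (UPR) — the
endoplasmic-reticulum stress program whose interactome, centered on the
chaperone BiP/HSPA5, can be retrieved from STRING for many organisms and
compared as a family of undirected graphs.

The package is for systems biologists who want to go beyond a table of
centralities: given one or more PPI networks (STRING-style TSV exports, or
seeded synthetic stand-ins), it computes

* the **descriptor suite** — per-node degree k(x), closeness
  C(x) = (Σ_y d(x,y))⁻¹, raw betweenness B(x), clustering CC(x),
  eccentricity; per-network density D = 2M/(N(N−1)), diameter, barycenter
  (argmin eccentricity), Louvain modularity Q, average path length
  l = (N(N−1))⁻¹ Σ_{i≠j} d_ij and efficiency
  E = (N(N−1))⁻¹ Σ_{i≠j} d_ij⁻¹ — plus size-normalized variants
  (k/(N−1), (N−1)·C(x), min-max betweenness);
* **configuration-model null ensembles** — R degree-preserving
  randomizations, z = (x−μ)/σ scores of native aggregates, paired Wilcoxon
  signed-rank tests against the ensemble, cross-network Kruskal–Wallis with
  Bonferroni correction, Pearson correlations and UPGMA dendrograms;
* the **Generalized Hamming Distance**
  dGHD(X,Y) = (N(N−1))⁻¹ Σ_{i≠j} (x′_ij − y′_ij)², on globally mean-centered
  adjacency weights, between any two same-size networks and on average
  against an ensemble;
* **robustness** under random and degree/closeness/betweenness-targeted
  attacks — the trace of largest-connected-component fractions G_i = n_i/N,
  the robustness integral R = N⁻¹ Σ G_i, the efficiency drop
  ΔE_i = (E−E_i)/E, and detection of ≥10% LCC collapse jumps;
* **structural controllability** of dx/dt = Ax + Bu — minimum driver nodes
  N_D via maximum matching on the bipartite out/in doubling, enumeration of
  alternative minimum sets, and verification through the Kalman rank
  condition rank(B, AB, …, A^{N−1}B) = N.

Result containers are S4 classes (`MetricTable`, `NullEnsemble`,
`GHDResult`, `AttackTrace`, `ControlSystem`, `DriverResult`) with validity
checks and accessors; networks are plain igraph objects.

## Worked example

A small synthetic UPR-like interaction file ships with the package:

```r
library(UPRnet)
f <- system.file("extdata", "example_interactions_synthetic.tsv", package = "UPRnet")
g <- readInteractionTSV(f)             # keeps scores >= 0.400, collapses duplicates
c(igraph::vcount(g), igraph::ecount(g), edgeRecordCount(g))
#> 12 14 28

tab <- normalizeMetrics(networkAggregates(g, nodeMetrics(g), seed = 1))
networkStats(tab)[c("density", "diameter", "barycenter", "modularity", "nCommunities")]
#> density 0.212  diameter 7  barycenter "HSPA5"  modularity 0.390  communities 3
```

Two interactions (scores 0.390 and 0.350) fall below the medium-confidence
threshold of 0.400 and are dropped, leaving 12 proteins and 14 undirected
edges (28 directed records, the STRING double-listing convention). The
barycenter — the minimum-eccentricity "absolute center" — is the BiP
chaperone HSPA5, as in the curated organism networks.

```r
ensembleZScores(g, R = 10, seed = 1)
#>           metric  native     mu  sigma      z defined
#> 1   avgCloseness  0.0331 0.0558 0.0560 -0.406    TRUE
#> 2 avgBetweenness 10.5000 7.7333 1.6652  1.661    TRUE
#> 3  avgClustering  0.2194 0.1161 0.0773  1.336    TRUE
```

The native closeness sits below its degree-matched randomizations and the
clustering above them — the ensemble shuffles the wiring, not the degrees.

```r
tr <- runAttack(g, attackOrder(g, "betweenness", "descending"))
robustnessR(tr)
#> 0.243
detectJumps(tr)
#>  step  node deltaG
#>     1 HSPA5  0.417
#>     4  ATF6  0.250
#>     5  XBP1  0.167
```

Removing the hub first collapses the LCC by 42% in one step; the robustness
integral 0.243 is far below the ascending-order value, the signature of a
hub-dominated topology.

```r
enumerateDriverSets(g, seed = 1)
#> DriverResult: N_D = 1 driver node(s), 12 minimum set(s)
#>   maximum matching size 12; Kalman-verified: TRUE
```

A perfect matching in the bipartite doubling means a single input signal —
injectable at any of the 12 proteins — suffices for full structural control
of this small network.

The multi-network pipeline (`analysisConfig()` + `runFullAnalysis()`) runs
all of the above over a set of networks and writes the per-network and
cross-network report bundle as TSV/JSON.

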