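---
title: "Statistical mechanics of protein-protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical mechanics of protein-protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(UPRnet)
library(igraph)
```

## Scope and model

UPRnet analyzes undirected protein-protein interaction (PPI) networks — the
motivating case being the unfolded protein response (UPR) interactomes of
twelve organisms, curated from STRING at the medium-confidence score cutoff
of 0.400 — through four complementary lenses:

1. **Descriptors.** Degree, closeness, betweenness, clustering, eccentricity
   per node; density, diameter, barycenter (the minimum-eccentricity node,
   in these networks the BiP/HSPA5 chaperone), Louvain modularity, average
   path length and efficiency per network; and size-normalized variants so
   networks of 57-231 nodes are comparable.
2. **Null ensembles.** Degree-preserving configuration models, z-scores of
   the native aggregates against the ensemble, and a non-parametric battery
   (paired Wilcoxon signed-rank within organisms, Kruskal-Wallis with
   Bonferroni correction across organisms, Pearson correlations, UPGMA
   dendrograms). The Generalized Hamming Distance (GHD) quantifies how far a
   native wiring sits from its randomizations.
3. **Robustness.** Sequential node-removal attacks (random, or targeted by
   degree/closeness/betweenness), the robustness integral
   R = N^-1 Σ G_i over the largest-connected-component (LCC) fractions, the
   efficiency-drop trace, and detection of sudden LCC collapses ("jumps").
4. **Controllability.** Structural controllability of the linear dynamics
   dx/dt = Ax + Bu on the network, minimum driver nodes via maximum matching
   on the bipartite out/in doubling, enumeration of alternative minimum
   sets, and verification through the Kalman rank condition.

## Conventions and parameter choices

Several conventions are fixed once, with the following rationale.

**Edge records versus edges.** STRING TSV exports list each undirected
interaction in both directions. Summary tables built on them therefore
report *record* counts (2M). Internally every graph is undirected and
simple; `edgeRecordCount()` exposes the 2M convention, and
`recordDensity(N, records)` reproduces published densities, which equal
records/(N(N-1)) = 2M/(N(N-1)).

**Score threshold.** Ingestion keeps records with combined score >= 0.400
(inclusive), the medium-confidence convention; the threshold is an argument,
never hard-coded downstream.

**Closeness on disconnected graphs.** The raw definition
C(x) = (Σ_y d(x,y))^-1 is undefined when unreachable pairs exist, so the sum
is restricted to the node's component, and isolated nodes score 0. The
distance-based *network* aggregates (diameter, barycenter, path length,
efficiency) fall back to the largest connected component with a warning:
these networks are analyzed through their LCC.

**Betweenness scale.** Betweenness is reported as raw shortest-path pair
counts, the scale on which the curated per-organism summaries sit
(about 25-181 for these network sizes); the min-max normalized variant is a
separate column. Normalized degree is k/(N-1) and normalized closeness
(N-1)·C(x), the standard removals of the size dependence.

**Barycenter ties** are broken by smaller total distance, then
lexicographically — determinism matters more than the arbitrary choice.

**Louvain** runs at resolution 1.0 with the seed controlling traversal
order; an edgeless network is defined to have one singleton community per
node and Q = 0 (the modularity formula is degenerate at M = 0).

**z-scores** use the sample (n-1) standard deviation over the R = 10
replicate aggregates — the small-ensemble convention; σ = 0 is reported as
an undefined flag rather than an infinite score. The paired signed-rank test
pairs each node's native value with that node's mean across the ensemble.

**GHD.** Weights are the binary adjacency entries, mean-centered *globally*
over ordered off-diagonal pairs. The distance is the mean *squared*
difference of centered weights. With global centering a linear (unsquared)
sum telescopes to zero for every pair of same-size networks — a useful
diagnostic identity, available as `mode = "linear"`, but useless as a
distance; the squared form is therefore the default and the only mode whose
zero set is exactly the coincidence of centered matrices.

**Attack conventions.** Rankings are static: metrics are computed once on
the intact network and the order fixed, matching the protocol of ranking
then removing ("the least important nodes first" is `direction =
"ascending"`). G_i is normalized by the *intact* N throughout. The
efficiency trace divides the surviving sum of inverse distances by the
intact network's N(N-1) pair count: with this convention ΔE_i = (E - E_i)/E
is guaranteed to lie in [0,1] and to be non-decreasing, whereas recomputing
efficiency on the shrinking LCC can paradoxically *rise* when a peripheral
node is removed (deleting an endpoint of a 3-path lifts LCC efficiency from
5/6 to 1). Jumps are flagged when G drops by at least the threshold
(inclusive, default 0.10).

**Controllability.** Undirected edges are treated as two opposed directed
influences — the only consistent reading of a symmetric state matrix.
Generic weights are drawn independently per directed influence (magnitude
uniform in [0.5, 1.5], random sign): independent parameters are what
structural controllability theory assumes, and binary weights can produce
non-generic rank deficiencies. The Kalman test builds the Krylov blocks
B, AB, A²B, ... with per-block rescaling — a positive column scaling that
leaves rank unchanged but keeps A^k B in floating-point range for any k —
and stops as soon as a block contributes no new direction (the Krylov space
is then A-invariant). Rank is accumulated by re-orthogonalized Gram-Schmidt
at tolerance 1e-8 on unit-normalized columns; a failed verification is
retried with a second weight seed before being reported.

The driver-node count follows the maximum-matching principle, with two
refinements that keep it exactly equal to the brute-force minimum over
dedicated single-node inputs:

* the count floors at one driver *per connected component* (a perfectly
  matched component still needs an input injected somewhere);
* for directed inputs the bare matching bound is occasionally unachievable
  with dedicated inputs (two source cycles feeding one sink leave one
  unmatched node, yet no single input reaches both cycles), so the search
  widens until a set satisfies both structural conditions — accessibility of
  every node from the input set and a matching saturating all non-input
  in-copies (Lin's conditions). For undirected PPI networks the matching
  bound is always achieved.

Enumeration of alternative minimum sets walks size-N_D subsets in index
order with matching-deficiency pruning, deduplicates by node set (not by
matching), and truncates at a cap (default 64) with a flag.

**Exact-versus-floating rank.** Rational arithmetic for small systems was
considered and rejected: base R has no arbitrary-precision rationals, and
the scaled Krylov/Gram-Schmidt construction with a second-seed retry decides
every case in the validation corpus identically to the combinatorial
(exact) structural test, which is what the package actually uses to decide
minimality. The Kalman route is retained as an independent verification, not
as the decision procedure.

## The synthetic generator

No accession-level network data are redistributed, so seeded generators
reproduce the statistical shape the analysis assumes:

* `canonicalGraph()` builds the analytic fixtures (star, path, cycle,
  complete, two-clique bridge, empty) whose metric values are known in
  closed form.
* `sampleGraphicalNetwork()` realizes explicit degree sequences exactly
  (Havel-Hakimi construction followed by seeded degree-preserving
  double-edge swaps — the switching randomization; it terminates on every
  graphical sequence, including tight hub-dominated ones), or draws
  planted-partition graphs for community-recovery checks (defaults p_in =
  0.9, p_out = 0.05, two blocks of 15).
* `emulateOrganism()` matches a curated organism's exact node and edge-record
  counts (hence its published density, which depends on N and M alone), puts
  a dominant hub — 0.6(N-1) neighbors, at least the mean degree — under the
  organism's barycenter protein label, and fills the remaining nodes with a
  ranked power-law tail (exponent 2.1, the scale-free regime reported for
  PPI networks) rescaled to the exact record count.

What the generator does *not* emulate: the true STRING wiring, ortholog
structure, score distribution, or the specific community memberships of the
curated networks. Tests passing on synthetic networks therefore validate the
*operations* (metrics, ensembles, attacks, matchings) and the published
self-contained quantities, not organism-specific table values that require
the original downloads.

Configuration models use the same switching realization, so replicates
preserve the degree sequence *exactly* — the validity method of
`NullEnsemble` asserts this for every replicate.

## Problem sizes used in validation

The shipped validation suite runs on: the canonical fixtures (4-12 nodes),
seeded corpora of 100 random graphs with at most 8 nodes for the
brute-force oracle comparisons (descriptors by BFS plus path enumeration;
driver counts by exhaustive subset search under the generic-weight Kalman
test), 30-node planted-partition graphs for community recovery, an
exhaustive search over all 115975 partitions of the 10-node two-clique
bridge for the modularity optimum, and emulated organism networks (57-216
nodes) for end-to-end runs. These sizes make the brute-force oracles exact
while keeping the whole suite comfortably fast; the operations themselves
scale to the full curated networks (57-231 nodes) without adjustment.

## Known limitations

* Published organism-specific table values that depend on the undeposited
  STRING downloads (per-organism z-scores, GHD averages, driver identities)
  are not acceptance surfaces; the pipeline ingests such downloads when the
  user supplies them.
* The signed-rank test falls back to the normal approximation (with
  continuity correction) in the presence of ties or beyond 25 non-zero
  differences, as the exact distribution is then unavailable or expensive.
* One reported behavior is deliberately not reproduced: the original
  driver-node analysis reports *no* driver set for one organism (the bovine
  model) without stating a mechanism. The matching algorithm always produces
  a set — an empty result is not a possible outcome of the method as
  specified — so this package always returns one.
* Weighted-graph metrics, eigenvector/PageRank centralities, FDR-style
  multiplicity corrections and time-domain simulation of the control system
  are out of scope.

## A worked mini-analysis

```{r, eval = FALSE}
nets <- list(
  fly   = emulateOrganism("Drosophila melanogaster", seed = 1),
  yeast = emulateOrganism("Saccharomyces cerevisiae", seed = 1)
)
cfg <- analysisConfig(nets, ensembleSize = 10, seed = 1)
bundle <- runFullAnalysis(cfg)
bundle$descriptors      # per-network summary in the published layout
bundle$robustness       # R per attack strategy
bundle$drivers          # minimum driver nodes and alternative set counts
```
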