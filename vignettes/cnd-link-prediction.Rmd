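---
title: "Predicting missing links from common neighbors and distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting missing links from common neighbors and distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cndlink)
```

## The model

`cndlink` treats link prediction as a ranking problem on an undirected
simple graph G = (V, E) with N nodes and m edges. A fraction of the edges
is hidden as a probe set E^P; the remainder is the training graph
G′ = (V, E^T). A predictor assigns a likelihood score to every candidate
pair (the non-adjacent pairs of G′) and is judged by how highly it ranks
the hidden edges.

The package's central score combines the two cheapest structural signals:

$$ s_{ij} = \mathrm{CN}_{ij} + \frac{1}{d_{ij}}, $$

with $\mathrm{CN}_{ij} = |\Gamma(i) \cap \Gamma(j)|$ the common-neighbor
count and $d_{ij}$ the shortest-path (hop) distance in the training graph;
$1/d_{ij}$ is taken as 0 when no path exists. Two properties follow
immediately and are pinned by the test suite:

* candidate pairs with a common neighbor sit at distance exactly 2, so for
  them $s = \mathrm{CN} + \tfrac12$ and the score ordering is the plain CN
  ordering;
* among pairs with no common neighbor the score is strictly decreasing in
  distance, with disconnected pairs strictly last.

The score therefore behaves like the classical CN index where CN evidence
exists, and falls back to closeness — the tendency of real networks to
grow short loops — where it does not.

### The two-budget selection rule

Top-L prediction (L fixed to the probe size) needs to decide how many of
the L slots to spend on each of the two candidate pools. The realised
fraction $c_r$ of probe links whose endpoints share a training-graph
neighbor is unobservable, but the analogous fraction over *observed*
edges,

$$ c_n' = \frac{1}{|E^T|} \sum_{(i,j) \in E^T} \delta_{ij}, \qquad
   \delta_{ij} = \mathbf{1}\{\Gamma(i) \cap \Gamma(j) \neq \emptyset\}, $$

is a natural plug-in estimate: hiding a small uniform sample of edges
perturbs neighborhoods only slightly, so edges and missing links close
triangles at similar rates. `predict_cnd()` allocates
$\mathrm{round}(c_n' L)$ predictions to the with-CN pool (ranked by
$s_{ij}$, i.e. by CN) and the rest to the no-CN pool (ranked by $s_{ij}$,
i.e. shortest distance first). If a pool runs out of candidates the
shortfall transfers to the other pool, so exactly L links are returned
whenever the candidate universe allows; the transfer is reported with a
`message()` since on realistic inputs at 10–20% probe fractions it should
never trigger.

The accuracy of the plug-in estimate is measurable within the package:
`partition_probe()` yields $c_r$, `training_cn_coefficient()` yields
$c_n'$, and `estimator_diagnostics()` summarises their agreement (RMSE and
Pearson correlation) across networks. On the bundled synthetic suite the
acceptance script recomputes both at every run.

### Baselines

Eleven classical indices are implemented behind the same scoring surface
(`score_pairs()`): CN, Salton, Jaccard, Sørensen, hub-promoted,
hub-depressed, Leicht–Holme–Newman, Adamic–Adar (natural logarithm, the
standard convention), Resource Allocation, Preferential Attachment, and
the Local Path index $A^2 + \beta A^3$ with $\beta = 0.01$ by default.
Matrix-product indices (CN counts, AA/RA weights, LP) are computed with
sparse `Matrix` products, never dense powers. Two conventions keep the
rankings total: indices with a vanishing denominator (isolated endpoints)
score 0, and Jaccard and Sørensen — monotone transforms of one another —
are expected to produce identical rankings, which the tests assert via
identical AUC and Precision on shared splits.

## Evaluation protocol

* **AUC.** The default is the exact Mann–Whitney statistic computed by
  midranks over all (probe, non-link) score comparisons, with half credit
  for ties; `auc_sampled()` offers the Monte-Carlo estimator (which the
  exact form is the limit of) for very large graphs. The negative class is
  the true non-links of the *original* graph, i.e. candidates of the
  training graph minus the probe.
* **Precision.** Fraction of the top-L predictions that are probe links,
  with L = |E^P| enforced — a prediction list of any other length is a
  protocol error, not a different operating point.
* **No-CN Precision.** The same count restricted to probe links whose
  endpoints share no training-graph neighbor, divided by the number of
  such links. The denominator is the size of that probe subset, not L;
  when the subset is empty the metric is undefined and reported as `NA`,
  never silently 0. CN-family baselines recover exactly zero of these
  links on every realization — they score the whole no-CN pool at 0 — and
  this qualitative separation is asserted by the acceptance tests.

### Randomness, seeds and tie-breaking

A benchmark run (`run_benchmark()`) is a pure function of its inputs and a
single `master_seed`. Child seeds for each (network, fraction,
realization) are derived by hashing, so adding a method or reordering the
method list never changes the splits: method comparisons are paired, as
mean-difference tables over shared splits require.

Equal scores are frequent (integer CN counts; a handful of distinct
distances), so tie handling is part of the method, not a detail. Within
each realization a single random tie-breaking permutation is drawn and
shared by *all* methods: ties within one method's ranking are resolved
uniformly at random (unbiased Precision), while monotone-equivalent
methods (Jaccard/Sørensen; CND restricted to the with-CN pool vs CN)
resolve their common tied blocks identically. A fully deterministic
lexicographic mode (`tie_break = "deterministic"`) exists for
bit-reproducible single predictions.

Rounding of the probe size and of the with-CN budget uses
round-half-away-from-zero, so 10% of 78 edges is 8 and the two budget
shares always sum to L.

## Network statistics

`network_profile()` bundles the statistics used to characterise benchmark
networks; each has a documented convention chosen where the standard
definitions leave room:

* *Clustering* `c`: mean of the local clustering coefficients over all N
  nodes, degree-0/1 nodes contributing 0.
* *CN coefficient* `c_n`: fraction of edges whose endpoints share a
  neighbor. Its training-graph analogue is the plug-in estimator above.
* *Average distance*: mean over reachable unordered pairs only, with the
  unreachable count attached as an attribute — a disconnected component
  must not make the statistic infinite.
* *Assortativity* `r`: Pearson correlation of endpoint degrees over edges
  counted in both orientations; degenerate (zero-variance) cases return
  `NaN` with a warning rather than a misleading 0.
* *Degree heterogeneity* `H`: the standard moment ratio
  $\langle k^2 \rangle / \langle k \rangle^2$, equal to 1 exactly for
  regular graphs.
* *Pseudo-distance distribution* `p_d`: for each edge, the distance
  between its endpoints after deleting that edge; bridge edges go to a
  separate infinite bin. The identity $p_2 = c_n$ (an edge has
  pseudo-distance 2 iff its endpoints share a neighbor) holds to machine
  precision and is asserted property-style across graph types.

Unreachability is always represented as `Inf` — distinct from every finite
value and handled explicitly by downstream code (`1/Inf = 0` in the score;
a separate bin in `p_d`; exclusion plus a count in the average distance) —
never as a large finite sentinel.

## The synthetic suite

`synthetic_suite()` fixes eight seeded networks — three Watts–Strogatz
(n = 100–200, ring degree 4–10, rewiring 0.05–0.2), two Barabási–Albert
(m = 2, 4) and three Erdős–Rényi (mean degree roughly 3–8) — chosen to
span CN coefficients from about 0.05 to 0.95, the range covered by the
classical small benchmark collections, at sizes (100–200 nodes) where the
full exact protocol runs in seconds. The suite emulates the *spread* of
clustering regimes; it does not emulate community structure, degree–degree
correlations of real social networks, or their specific degree sequences.
Passing estimator diagnostics on this suite therefore shows that
$c_n'$ tracks $c_r$ across clustering regimes, not that either is
unbiased on any particular real network.

Benchmark problem sizes used by the tests and the acceptance script — the
34-node karate fixture with 20 realizations at a 10% probe, and the
100–200-node synthetic suite — were chosen as the smallest sizes at which
the protocol's means are meaningfully comparable to published small-network
benchmarks.

## Known limitations

* **Distance is coarse.** Within the no-CN pool all candidates at the same
  distance tie, and on small dense graphs the distance-3 class alone can
  be orders of magnitude larger than the no-CN budget. With unbiased
  random tie-breaking, the expected share of hidden links recovered from a
  tied block equals the budget share of the block — typically a few
  percent. Reported no-CN precision under this package's tie policy is
  therefore a conservative, unbiased estimate; any scheme that orders
  within distance classes (by path counts, degree products, or an
  arbitrary but fixed candidate order) changes this metric substantially
  in either direction without changing the score's definition. This is
  the main source of irreproducibility when comparing implementations of
  distance-based predictors.
* The exact AUC and the full distance matrix are quadratic in N; beyond
  ~10^4 nodes use `auc_mode = "sampled"` and expect the CND scorer to
  dominate runtime.
* Only single uniform random probe removal is implemented — no temporal or
  stratified splits.
* Weighted, directed and signed networks are out of scope; directed or
  multi-edge input is canonicalised (with a warning) to the undirected
  simple form.
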