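---
title: "Inferring aerial connectivity networks from backward trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring aerial connectivity networks from backward trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Air masses carry microbial propagules over hundreds of kilometres, and the
question for a surveillance design is which portions of a territory are
*recurrently* connected by this transport, and when. `airnet` answers it
with spatio-temporal networks. The territory is gridded into `N` cells;
for every cell and every day a backward trajectory records the hourly
positions the arriving air mass visited during the previous 48 h. Day `t`
gives a binary directed network: `E_t(j, i) = 1` when the trajectory
arriving at cell `i` passed over cell `j`. Averaging the daily matrices
over a day subset `S` gives the weighted network
`E_S(i, j) = Σ_{t∈S} E_t(i, j) / |S|`, whose weights are fractions of days
with a connection — naturally in `[0, 1]` and directly interpretable
(0.10 = connected on 10 % of the days of `S`).

Assumptions worth keeping in mind:

* A single trajectory per cell and day (one arrival time) represents that
  day's transport into the cell.
* Containment is tested at the hourly positions only, with no segment
  interpolation between them. At the default mesh (74 km) an air mass
  moving at typical synoptic speeds cannot jump a cell within an hour, so
  interpolation would add nothing; much finer meshes would need it.
* Altitude is ignored: a trajectory "passes over" a cell in the 2-D sense.
* Edges are unweighted within a day; recurrence, not intensity, is what
  the aggregation measures.

### Conventions fixed here

The direction convention is **source → arrival** everywhere: the edge
`j → i` means air moved from `j` to `i`. The diagonal is forced to zero —
every trajectory trivially passes over its own arrival cell, and keeping
self-loops would saturate the diagonal and distort density and strengths.

## Effective distances and the metric suite

Shortest-path algorithms treat weights as costs, while connection
frequencies are the opposite. After row-standardizing `E_S` into `P`
(all-zero rows stay zero), weights become effective distances
`ED(i, j) = 1 − ln P(i, j)`; entries with `P = 0` are non-edges. The
natural logarithm follows the effective-distance literature; finite
entries are ≥ 1, with equality exactly when a node has a single
out-neighbour. `ED` is invariant to a global rescaling of the weights
because the row-standardization absorbs constants.

Diameter and average shortest path are computed with Dijkstra on the `ED`
digraph over all **reachable** ordered pairs; unreachable pairs are
excluded and their count reported rather than folded in as infinities.
Density is the weight sum over `N(N−1)`. Transitivity is the triplet
analogue of density; since the classical binary formula has several
weighted generalizations, the package fixes one: on the symmetrized matrix
`W = (E + Eᵀ)/2`, each connected triplet contributes the arithmetic mean
of its two tie weights, and the coefficient is the closed-triplet value
over the connected-triplet value. It reduces exactly to the binary global
clustering coefficient on unweighted graphs (the test suite checks this
against `igraph`). Strength correlation is the Pearson correlation across
nodes of in-strength versus out-strength; the report labels it
`strength_correlation` even though "degree correlation" is a common
header for the same quantity.

Degenerate inputs are signalled, not silently patched: no connected
triplet → transitivity 0 with a warning; constant strengths → `NA` with a
warning; a fully disconnected network has no shortest-path statistics and
errors.

## Cut distance and seasonal clustering

Two same-node-set weighted digraphs are compared by the cut distance

d(A, B) = max over bipartitions (Q, Q̄) of |Σ_{i∈Q, j∉Q} (A_ij − B_ij)| / N²

restricted to complementary subset pairs. The `1/N²` normalization makes
values comparable across grid sizes (a `normalized = FALSE` switch
restores the raw maximum). Exact enumeration over the `2^N − 2`
non-trivial subsets is feasible to `N = 20` and refuses beyond; the GA
route handles larger networks. The GA encodes a bipartition as a binary
membership chromosome (population 50, 200 generations, per-gene mutation
0.05, elitism 2, binary tournament selection, uniform crossover) and is
memetic: each generation the incumbent is refined by steepest-ascent
single-bit local search — computed incrementally in `O(N²)` per sweep from
the signed cross-partition sum — and two hill-climbed random immigrants
maintain diversity. Empty or full subsets get fitness 0 rather than being
repaired. The GA value is a lower bound on the exact distance by
construction, and its best-per-generation trace is nondecreasing under
elitism; the test suite measures its agreement with exact enumeration on
random `N = 10` pairs.

Monthly networks are compared pairwise (seeds for the GA derive
deterministically from one base seed, one per pair) and clustered with
average-linkage agglomerative clustering cut at `k = 2`. Average linkage
was chosen as the least-committal standard linkage for a pseudometric
without strong cluster-shape assumptions.

## Pareto front in the weight–distance plane

Each non-null edge is a point (great-circle centroid distance, weight).
The edges worth sampling are those not dominated in both coordinates —
the Pareto front under *weak* dominance, so ties survive. "Close to the
front" needs a metric on axes with incommensurate units (km versus
day-fraction); the package min–max normalizes both axes within the cloud
and measures Euclidean distance to the front polyline (front points
joined in distance order), with a `score = "point"` alternative using
front vertices only. Selection of the `ceiling(fraction · n)`
lowest-scoring edges breaks ties by higher weight, then higher distance,
then record order, which makes selections nested as the fraction grows.

## Node relevance and the SI model

Betweenness and closeness are computed on the effective-distance digraph,
coherent with the diameter computation (inverse-weight costs are the main
alternative; ED was preferred so that all path-based quantities share one
cost model). Closeness is out-closeness over the reachable set, with the
reachable count reported alongside. Coreness is the classical k-shell
index on the binarized undirected skeleton; the various weighted k-shell
generalizations were deliberately avoided in favour of the classical
definition. Eigenvector centrality is the leading
**left** eigenvector of the weighted adjacency (incoming influence,
receptor-oriented), nonnegative and max-normalized; a switch gives the
right-eigenvector (source-oriented) reading. Both weighted strengths and
binary in/out-degrees are reported, since either reading of
"degree" appears in practice.

The SI model is deterministic: starting from one infected node, at each of
6 synchronous steps a susceptible node becomes infected when the maximum
weight among its infected in-neighbours exceeds 0.1. The threshold is read
as *strict* (`>`), configurable to `≥`; with day-fraction weights, 0.1
means "connected on more than 10 % of days". Percentages are over all `N`
nodes with the seed counting as infected, so the SI persistence of an
isolated node is `100/N`, not 0. Because infected sets only grow, the
"maximum percentage of infected nodes" equals the final percentage, which
is what the implementation returns. A useful identity — used as a test
invariant — is `mean(P) = mean(F)`: both equal total infections over `N²`.

## The synthetic generator

Real inputs are HYSPLIT-driven trajectories; the generator replaces them
with a transparent kinematic emulation so every stage is testable
end-to-end. Each month belongs to a wind regime (direction the air comes
*from*, mean speed, hourly Gaussian jitter on direction and speed);
backward integration steps one hour at a time along the regime bearing on
a 6371-km sphere, starting from the arrival centroid. Altitude is a
constant 500 m — the customary arrival altitude for near-surface transport
studies — and never enters the edge rule. Default study conditions used
throughout the tests: 48-h trajectories, 74-km mesh, speed 40 km/h with
15° direction and 5 km/h speed jitter, and a two-season calendar
(westerlies May–September, easterlies October–April) mirroring a
two-regime Mediterranean-like year. February 29 can be dropped so that
every year contributes 365 days; seven years then give 2555 daily
networks, and a 604-cell grid 1,543,220 trajectories.

What the generator does **not** emulate: curved or recirculating flows,
vertical motion and mixing, stagnation, spatially heterogeneous wind
fields, and trajectory-model error. Consequently, passing tests show the
pipeline's correctness and its ability to recover *planted* seasonal
structure; they say nothing about how sharply real seasons separate.

## Problem sizes and numerical choices

The test suite exercises: metric oracles (brute-force triplet enumeration,
Floyd–Warshall, direct Pearson) on 100 random digraphs with `N ≤ 12`;
GA-versus-exact cut distance on 100 random `N = 10` pairs (agreement
expected in ≥ 99); planted-season recovery on a 6×6 lattice over 24
months, 20 seeded replicates (exact recovery expected in ≥ 19); SI
reachability oracles on 50 random `N = 10` networks; Pareto dominance and
nesting on random clouds up to 120 edges. These sizes keep every oracle
exhaustive while the properties they check are size-independent.
Floating-point ties in the GA and in Pareto scoring are resolved by the
deterministic tie-break orders stated above; cut-distance equality is
asserted to `1e-12`, eigen-equation residuals to `1e-10`, and tdump
round-trips to the 6 decimal places the format stores.

## Limitations

* One trajectory per cell-day and a single arrival altitude; multi-height
  or multi-time ensembles would need several trajectory sets.
* The cut-distance bipartition objective is the complementary-subsets
  variant, not the general rectangle (two independent subsets) distance.
* The GA is a heuristic: its value is a certified lower bound only.
* Effective-distance paths depend on row-standardization, so node-level
  path metrics compare within a network, not across networks with very
  different out-degree structure.
* Grid cells are treated as planar for containment; at very high
  latitudes or very coarse meshes a projected grid should be supplied via
  `grid_from_cells()`.
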