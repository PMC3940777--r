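---
title: "Graphlet-orbit link prediction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphlet-orbit link prediction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphletLP)
```

# The problem and the model

Experimentally derived protein–protein interaction networks are noisy:
a substantial fraction of true interactions is missing and a fraction
of the recorded ones is spurious. Link prediction (LP) addresses both
at once by assigning every unordered node pair a score such that pairs
likely to interact rank high; replacing the edge set with the
top-ranked pairs de-noises the network.

`graphletLP` scores pairs from *graphlets*: connected induced subgraphs
on 2–5 nodes. Within a graphlet, the automorphism group partitions
nodes, edges, and non-adjacent pairs into *orbits* — the topologically
distinct positions. Enumerating all 30 graphlets on 2–5 nodes gives 73
node orbits, 68 edge orbits, and 49 non-edge orbits. Because LP must
describe the surroundings of a pair *without* revealing whether the
pair is currently linked, each non-edge orbit is reconciled with the
edge orbit obtained by adding the missing edge; the merged classes are
the 49 *node-pair orbits*. Edge orbits whose edge is a bridge have no
non-edge counterpart (deleting the edge disconnects the graphlet),
which is exactly why 68 edge and 49 non-edge orbits reconcile into 49
node-pair classes.

Counts over these orbits give, for a node, the *graphlet degree vector*
(node-GDV, 73 entries, first entry the degree) and, for a pair, the
node-pair-GDV (49 entries). Two scores are derived:

* **node-GDV-similarity** `S(u, v) ∈ [0, 1]`: one minus a weighted mean
  of per-orbit log-scale distances
  `D_i = w_i |log(u_i+1) − log(v_i+1)| / log(max(u_i, v_i)+2)`.
  The log keeps orbits whose counts span orders of magnitude from
  dominating; the normalising denominator makes each term
  scale-free.
* **node-pair-GDV-centrality** `C(u, v) = Σ_i d_i w_i log(c_i + 1)`:
  a monotone summary of how many graphlets the pair shares.

The LP score is `α·Ĉ + (1−α)·S` with `Ĉ` the min–max-normalised
centrality, so the mix favours pairs that are both topologically
similar and share a large extended neighbourhood.

## Assumptions

The network is undirected and simple, with opaque string node
identifiers (no identifier mapping is attempted). Scores are purely
topological; annotations enter only at evaluation time. All pairs —
including current edges — are scored, which is what lets de-noising
remove spurious edges as well as add missing ones.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.8 | centrality weight in the combined score (0 = similarity only, 1 = centrality only) |
| `weighted` | `TRUE` | multiply each orbit term of the centrality by the density of its edge-completed graphlet |
| `maxNodes` (catalog) | 5 | graphlet sizes used: 3, 3–4, or 3–5 nodes (node-GDVs always include the 2-node graphlet, i.e. the degree) |
| `beta` (Katz) | 0.005 | walk-length damping; the closed form requires `beta` below the reciprocal spectral radius, which the function checks |
| `epsilon` (LPI) | 0.005 | weight of the cubed-adjacency term |
| `fractions` | 0.05–0.5 | synthetic-noise levels (fraction of edges removed) |
| `nReplicates` | 5 | seeded removal replicates per noise level, compared by paired t-tests |

`alpha = 0.8` is the default because mostly-centrality mixes with a
small similarity contribution are the strongest configurations across
the evaluation tests; `alpha` is still a first-class argument and the
pipelines accept any grid. Restricted to 3-node graphlets there is a
single node-pair orbit whose completed graphlet (the triangle) has
density one, so weighted and unweighted centralities coincide and the
`alpha = 1` ranking equals shared neighbours — both equivalences are
enforced by tests.

## Orbit weights

The weight of orbit `i` is `w_i = 1 − log(o_i)/log(N)` with `N` the
orbit total of its taxonomy. The dependency count `o_i` is computed
from first principles: it is the number of distinct orbits touched by
the orbit's representative element *within its own graphlet*, over all
connected induced subgraphs containing it (itself included). Touching
an orbit therefore really does imply touching each of its `o_i`
dependencies, and heavily implied (redundant) orbits are down-weighted.
The degree orbit depends only on itself (`w_0 = 1`); a taxonomy with a
single orbit gets weight 1 by convention, avoiding `log(1)` in the
denominator. Published or user-derived weight tables can be supplied
verbatim through the `override` argument of `orbitWeights()`.

## Density weighting

The density weight of a node-pair orbit is `2m/(n(n−1))` of its
*edge-completed* graphlet, in (0, 1]. The completed graphlet is the
natural carrier of the pair's "if linked" structure: sharing 4-cliques
(density 1) then counts for more than sharing 4-paths (density 1/2).
This functional form — density as a multiplicative per-orbit factor
inside the centrality sum — is this package's design; alternatives
(e.g. density powers) would preserve the qualitative behaviour.

## Centrality functional form

The log-damped weighted sum `Σ d_i w_i log(c_i + 1)` mirrors the
rationale of the similarity measure: raw orbit counts differ by orders
of magnitude, and an undamped sum would be dominated by the most
frequent sparse orbits, defeating the density weighting. The form is
strictly increasing in every count, zero at zero, and collapses to a
monotone transform of the shared-neighbour count for 3-node graphlets,
which is the behaviour the measure family is designed around.

# Counting: algorithm and numerical choices

The catalog is built by exhaustive enumeration: all labelled graphs on
k ≤ 5 nodes (at most 2^10 masks), connectivity by BFS, isomorphism
classes by canonical form (minimum mask over all k! relabellings), and
automorphism groups by explicit permutation enumeration. Orbit
partitions are the exact group orbits, so the taxonomy totals are
analytic, not sampled.

Ordering is deterministic and documented: graphlets sort by (node
count, edge count, descending-sorted degree sequence, canonical mask);
orbits within a graphlet sort by representative degree. This
reproduces the conventional numbering of the 2–4-node graphlets (path
ends in node orbit 4 before middles in 5, outer path edges in edge
orbit 3 before the middle edge in 4, triangle edge orbit 2 reconciling
with the 3-path non-edge orbit 1 into node-pair orbit 1). Any
alternative numbering would permute orbit indices only; every score
sums over orbits, so rankings are unaffected.

Counting in a network uses ESU-style recursive connected-subgraph
extension (each connected node subset of size 2–5 visited exactly
once), implemented in C++, with classification by a precomputed table
from labelled adjacency masks to global orbit indices. Pair counting
masks the pair's own edge: a subset contributes to pair (u, v) when the
induced subgraph minus the (u, v) edge is connected, classified by the
non-edge orbit of the masked subgraph. Adding or removing the (u, v)
edge therefore never changes the pair's own GDV — the property the
reconciled orbits exist for. The counting kernel is verified, exactly,
against a naive oracle that enumerates every node subset and classifies
by independent (VF2) isomorphism, over a hundred seeded random graphs.

Other numerical conventions:

* Natural logarithms throughout; the base cancels in the similarity's
  ratio and only rescales the centrality uniformly.
* Centrality min–max normalisation before α-mixing puts the unbounded
  centrality on the similarity's [0, 1] scale; a constant centrality
  normalises to zero.
* Rankings break score ties lexicographically on the node-name pair
  (radix order, locale-independent), so every table, prediction file,
  and curve is bit-reproducible.
* AUROC/AUPR are computed by the trapezoid rule over the *complete*
  ranking; the 1 %-grid confusion table (k = 0–100 %) is the reporting
  grid. A perfect ranking thus scores exactly 1 and a reversed one 0.
  Precision at zero predictions is 1 by convention (the PR curve's left
  anchor); F-score is 0 where precision + recall is 0.
* Paired t-tests on replicate AUROCs report p = 1 for identical
  replicate vectors and degenerate to p = 0 (with a warning) when the
  differences are constant but non-zero.
* Hypergeometric enrichment uses the self-consistent margins: for GO
  sharing, all pairs of annotated universe nodes as population and the
  term-sharing pairs as successes; for external validation, the
  original network's non-edges over nodes shared with the reference as
  population and those present in the reference as successes. Zero
  eligible draws yield p = 1 and an undefined (NA) fraction.

# Synthetic fixtures: what they do and do not show

`makeNetwork()` generates Erdős–Rényi, Barabási–Albert, geometric, and
ring-with-chords graphs, seed-deterministically; `makeAnnotations()`
adds term sets with a tunable edge-assortativity knob (0 = annotations
independent of topology; 1 = every edge shares a term). Geometric
graphs are the main evaluation fixture because their clustered,
locally dense structure is the regime where neighbourhood-based LP is
informative; test-scale fixtures use n ≤ 60 nodes, where 3–5-node
counting completes in well under a second, and the whole suite runs in
seconds. The random-graph models do not reproduce the degree mixing,
experimental-bias structure, or annotation topology of real
interactomes, so passing tests demonstrate correctness and calibration
of the machinery — not biological performance claims. Real networks at
the 10^3-node, 10^4-edge scale are well within the counting kernel's
range (pair counting is quadratic in memory: roughly half a gigabyte
of pair-GDV rows at 1,600 nodes), and the CLI operates on ordinary
edge-list files for exactly that use.

# Limitations

* Exhaustive counting is exponential in the graphlet size in the worst
  case; dense networks beyond ~10^4 edges are better served by the
  restricted 3–4-node catalog. The per-root enumeration is
  embarrassingly parallel but runs single-threaded here.
* Random-walk-with-resistance, one published comparison measure, has no
  self-contained published definition and is not implemented; its
  score tables can be imported as plain data.frames.
* GO sharing uses direct term-set intersection; no ontology-graph
  ancestor propagation or semantic similarity.
* Only edge *removal* noise is generated; spurious-edge injection is
  out of scope (de-noising still removes spurious edges, since existing
  edges compete in the same ranking).
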