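---
title: "Multi-scale community detection: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale community detection: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscomm)
```

## The problem

Modularity maximization partitions a weighted graph by comparing observed
edge weights against a null expectation,

$$Q = \sum_{ij}\,(A_{ij} - \gamma P_{ij})\,\delta(g_i, g_j),$$

where $A$ is the adjacency matrix, $P$ the null model, $\gamma$ the
structural resolution parameter, and $\delta$ selects pairs sharing a
community. Sweeping $\gamma$ exposes community structure at different
topological scales, but each $\gamma$ is optimized independently, so labels
at neighboring resolutions are unrelated: there is no principled answer to
"is this community at $\gamma_1$ the same object as that community at
$\gamma_2$?" (the correspondence problem).

`mscomm` instead builds one multilayer problem: a copy of the graph is
placed at every $\gamma$ value of a grid, and each node is linked to its own
copy in the two neighboring layers with a coupling $\tau$. The joint quality
function is

$$Q = \frac{1}{2\mu} \sum_{ijxy} \left\{ (A_{ij} - \gamma_x P_{ij})\,
\delta_{xy} + \delta_{ij}\,\tau \right\} \delta(g_{ix}, g_{jy}),$$

with $\mu$ half the total node-layer strength (intra-layer strength plus
attached coupling weight). A single optimization then yields labels that are
globally meaningful across scales: a community that survives from one layer
to the next *is* the same community, and branching of a parent community
into children is directly observable. All downstream statistics (stability,
allegiance, consensus, reliability) consume these labels.

Two extensions use the same machinery: a **multiplex** variant couples two
graphs over the same nodes (for example structural and functional
connectivity) with an inter-modality coupling $\kappa$ at matching scale
layers, and a **multi-slice** variant couples an ordered sequence of graph
slices with an inter-slice coupling $\omega$ at matching scales, giving a
quality function over (node, slice, scale) triples.

## Null models and parameters

* **Uniform (geographic / constant Potts) null**, `null_model("uniform")`:
  $P_{ij} = c$ for all pairs. This is the default for the multi-scale sweep
  because it preserves a one-to-one relationship between edge weight and the
  scale at which a community dissolves (a block of internal weight $w$ turns
  unfavorable near $\gamma = w/c$), independent of node degree. The constant
  should be chosen so that scales are comparable across datasets:
  `null_constant()` offers the smallest positive weight (stable for sparse,
  heavy-tailed streamline-count-like matrices), the mean of positive
  weights, and the mean over all off-diagonal entries (stable for dense
  coherence-like matrices). Which mean convention suits a given dense
  dataset is a data question, not a modeling one, so both are provided.
* **Newman–Girvan null**, `null_model("newman_girvan")`:
  $P_{ij} = k_i k_j / 2m$. Used for single-scale baselines and for
  partitioning consensus graphs, where degree discounting is the standard
  choice.
* **$\tau$** (default used throughout the examples: 0.05–0.5): couplings
  near 0 decouple the layers (independent per-scale partitions); large
  couplings freeze one partition across all scales. Hierarchy is visible at
  middling values; the package treats $\tau$ as a single scalar for all
  nodes and layers, and only chains *adjacent* layers — the linear layer
  topology is what makes "scale" an ordered axis.
* **Gamma grids**: `make_gamma_grid(start, stop, step)` uses an inclusive
  endpoint rule with a relative tolerance of `step * 1e-9`, so grids whose
  step is not binary-representable (e.g. 0.0133) keep their intended layer
  count: `[0, 12]` by 0.05 gives 241 layers and `[0.0133, 1]` by 0.0133
  gives 75. Note that under this rule a range like `[0.95, 1.7]` by 0.01
  contains 76 points, not 75; the rule is applied uniformly rather than
  special-cased.

## The optimizer

The supra-modularity coefficients (including negative entries) are
optimized by a generalized Louvain heuristic implemented in C++: greedy
single node-layer moves in a seeded, per-pass reshuffled order, followed by
aggregation of communities into super-nodes, repeated until no move helps.
Numerical choices, all of which matter for reproducibility:

* moves are accepted only when they improve the raw quality by more than
  `1e-12` (absolute), preventing floating-point cycling;
* ties between equally improving target communities break toward the lowest
  community id, so identical seeds give bit-identical partitions;
* moves into an *empty* community are always considered alongside moves
  into neighboring communities — with negative coefficients, splitting off
  a singleton can be the best move, and omitting it silently biases the
  optimizer toward coarse partitions;
* quality is asserted non-decreasing across every phase, and aggregation is
  asserted to preserve quality exactly.

Exact maximization is intractable (the problem is NP-hard), so statistics
are computed over an ensemble of seeded restarts (`run_ensemble`; 100 runs
is the package default, and scaled-down studies in the tests use 20), and
on graphs small enough to enumerate, the tests verify that 20 restarts
attain the exhaustive optimum over all partitions.

## Stability, consensus, and their nulls

The **stability** of node $i$ at layer $x$ is the fraction of layers in
which $i$ carries the label it has at $x$; per node, spans over distinct
labels partition the layer axis (they sum to $L$ — a conservation identity
the tests assert). Thresholding spans gives per-node **stable-community
counts**, and a PCA of the node-by-layer stability matrix (layers centered,
explained variance from squared singular values) summarizes topological
heterogeneity as the number of components needed for 95% of the variance.

The **consensus** pipeline summarizes an ensemble: intra-layer allegiance
(co-classification fraction per node pair and layer) and inter-layer
allegiance (label persistence per node across adjacent layers) are
compared against a label-permutation null; significant entries keep their
allegiance weight in a consensus multilayer graph, which is partitioned
once more (Newman–Girvan per layer, $\gamma = 1$, couplings scaled by
$\omega = 1$). Design points:

* The null permutes node–label assignments independently within every
  (run, layer), preserving each layer's community-size histogram. Under
  such a permutation all off-diagonal entries of a layer are exchangeable,
  so the per-entry null distribution is obtained exactly by redrawing
  random node positions per replicate and run — this is how
  `allegiance_null` makes 1000 replicates cheap at hundreds of layers.
* The significance level and correction are genuinely open choices; the
  defaults are $\alpha = 0.05$ with Bonferroni over all tested entries,
  and 1000 permutation replicates. Reliability maps
  (`interlayer_reliability`) default to per-edge tests without correction,
  since they are descriptive.
* **Degenerate layers.** A layer that is a single community (or all
  singletons) in every run is its own permutation null, so none of its
  entries are significant and it resolves to isolated singletons in the
  consensus graph. This is the statistically honest outcome — there is no
  evidence against the null in a constant labeling — but it means the
  consensus partition of a *perfectly clean* graph reports its
  whole-graph regime as unresolved. Scale extraction
  (`consensus_scales`) therefore reads the hierarchy off non-singleton
  plateaus.

## The synthetic benchmarks

`nested_benchmark` plants a three-level hierarchy: 81 nodes in triads,
inside 9-blocks, inside 27-blocks, with a weight gradient of 0.02 per
sibling block within its parent so that same-sized blocks differ in average
weight (topological heterogeneity: stronger blocks dissolve at
proportionally higher $\gamma$). The default level weights
$\{0.551, 0.351, 0.151\}$ over a background of 0.05 were chosen so that,
with the uniform null at the smallest positive weight, all four scale
transitions fall inside the $\gamma \in [0, 12]$ sweep at comfortably
separated positions ($\gamma \approx 1$, $3.\!x$, $7.\!x$, $11.\!x$), each
level's weight band stays separated from its neighbors, and no dissolution
point coincides exactly with a grid value (base weights end in .001,
avoiding zero-gain ties). The generator is deterministic given its
specification; the seed only feeds optional weight jitter.

`rewire_null` produces the matched null: double-edge swaps randomize the
binary topology (degree sequence preserved exactly), then the original
weight multiset is re-laid onto the edges by a seeded random permutation
followed by greedy pairwise weight swaps that monotonically reduce the
squared error against the original strength sequence. A deterministic
rank-matching of weights to strength products was rejected by design: it
manufactures a nested threshold graph — a spurious, highly stable
hierarchy — whereas the greedy randomized variant approximates strengths
(correlation above 0.9 on the benchmark, measured in the tests) while
keeping the arrangement random. Weight multiset and degrees are exact
invariants; strengths are approximate by necessity.

`dynamic_benchmark` emulates two nested timescales of community dynamics:
within a slow epoch the active partition alternates at the fast period, and
the active pair of partitions rotates at the slow period. On the resulting
multi-slice problem, small $\omega$ recovers the fast switching and large
$\omega$ the slow structure.

What the generators do *not* emulate: realistic streamline-count or
coherence weight distributions (beyond heavy-tail versus narrow unimodal
contrasts), measurement noise between repeated observations of the same
graph, and spatial embedding. Tests passing on these benchmarks therefore
certify the machinery — construction, optimization, statistics, nulls —
not the empirical claims one might make about any particular dataset.

## Problem sizes and runtime

The full synthetic study used by the test-suite and the acceptance script
runs the 81-node benchmark over 241 layers (19 521 node-layers, about 1.6
million supra-modularity coefficients) with a 20-run ensemble, 1000
permutation replicates and the consensus optimization, in well under a
minute on one core; the same pipeline is run twice (benchmark and rewired
null). Enumeration oracles are restricted to at most 8 node-layers
(Bell(8) = 4140 partitions).

## Known limitations

* The consensus of degenerate layers is all-singleton (see above); callers
  comparing against naive expectations should use `consensus_scales`.
* Louvain is a local heuristic: on adversarial near-tie landscapes
  different seeds give different partitions. That degeneracy is the reason
  the ensemble/consensus layer exists; single-run output should not be
  interpreted alone.
* The multiplex builder supports exactly two modalities, and couplings are
  uniform scalars ($\tau$, $\kappa$, $\omega$); per-node or per-layer
  coupling heterogeneity is out of scope.
* `leaf_order_nodes` solves optimal leaf ordering exactly by dynamic
  programming; it is intended for node counts in the hundreds, not tens of
  thousands.
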