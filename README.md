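# mscomm — multi-scale community detection in weighted networks

Many weighted networks — brain connectivity graphs most prominently — are
organized hierarchically: tightly knit modules nest inside larger, looser
ones. Sweeping the resolution parameter γ of modularity maximization
exposes the different scales, but each γ is optimized independently, so
there is no principled way to say whether a community at one resolution is
the *same* community at another (the correspondence problem).

`mscomm` solves one joint problem instead. Copies of the graph are placed
at every γ value of a grid and each node is linked to its own copy in the
neighboring layers with a coupling τ, giving the multi-scale modularity

    Q = (1 / 2μ) Σ_{ijxy} { (A_ij − γ_x P_ij) δ_xy + δ_ij τ } δ(g_ix, g_jy)

which is maximized once, by a generalized Louvain heuristic, over all
node–layer pairs. Community labels are then directly comparable across
scales: branches of the dendrogram of communities are observable as labels
splitting between layers. On top of this the package provides

* node **stability** across scales, stable-community counts, community
  number/size curves, and a PCA heterogeneity summary;
* **allegiance** matrices over seeded optimization ensembles, with
  label-permutation nulls, significance-thresholded **consensus**
  partitions and inter-layer **reliability** ratios;
* a two-modality **multiplex** extension (coupling κ between, say,
  structural and functional connectivity) and a **multi-slice** extension
  (coupling ω between time slices) of the same quality function;
* cross-graph allegiance **correlation maps**, spatial contiguity
  statistics with permutation nulls, and optimal leaf-order node sorting;
* seeded **synthetic generators**: planted nested-hierarchy benchmarks,
  matched strength-preserving rewired nulls, and a two-timescale dynamic
  benchmark — so the whole pipeline is testable without external data.

Intended users: network scientists and neuroimaging researchers analyzing
weighted adjacency matrices (dense TSV/CSV or edge lists).

## Worked example

The bundled benchmark plants 81 nodes in triads inside 9-blocks inside
27-blocks, with weight gradients so same-sized blocks differ in strength:

```r
library(mscomm)

bench <- nested_benchmark()
bench$graph
#> <weighted_graph> 81 nodes, 3240 positive edges, total weight 370.4

spec <- multiscale_spec(bench$graph,
                        gamma_grid = make_gamma_grid(0, 12, 0.05),
                        tau = 0.05,
                        null = null_model("uniform", mode = "min_positive"))
b <- build_multiscale(spec)
b
#> <supra_modularity> (multiscale) 19521 node-layers, 1596186 stored coefficients, mu = 90241.5

ens  <- run_ensemble(b, n_runs = 20, base_seed = 1)
cons <- consensus_partition(ens, consensus_config(n_runs = 20, seed = 1))
sc   <- consensus_scales(cons$partition)
sc$scales[, c("start_layer", "end_layer", "gamma_start", "gamma_end",
              "n_nonsingleton", "max_size")]
#>   start_layer end_layer gamma_start gamma_end n_nonsingleton max_size
#> 2          21        61        1.00         3              3       27
#> 5          78       141        3.85         7              9        9
#> 9         159       241        7.90        12             27        3
sc$has_singleton_scale
#> [1] TRUE
```

Reading: the consensus over 20 seeded optimizations recovers the planted
hierarchy as three plateaus — 3 communities of 27 nodes for γ in (1, 3],
9 communities of 9 for γ in (3.85, 7], 27 triads for γ in (7.9, 12] — and
the hierarchy dissolves into singletons within the sweep: four nested
scales, each matching the planted labels exactly (adjusted Rand index 1 in
the test suite). Node-level summaries come from the same labels:

```r
s <- stability_matrix(cons$partition)
summary(count_stable_communities(s, threshold_pct = 10))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   1.000   2.000   3.000   2.444   3.000   3.000
heterogeneity_pca(s)
#> [1] 3
```

i.e. a typical node belongs to about 2–3 communities that each persist over
more than 10% of the γ range, and three principal components explain 95% of
the variance of the stability matrix.

A thin command-line front end (`exec/mscomm`) wraps the same functions:
`mscomm synth nested`, `mscomm detect --config cfg.json`,
`mscomm compare --config cfg.json`, with JSON run configurations and
hash-stamped artifacts for reproducibility.

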