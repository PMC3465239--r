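# spokenet

Tools for testing what the declining clustering spectrum C(k) of biological
networks actually measures.

## The science

For many metabolic, protein-interaction and regulatory networks the mean
clustering coefficient of degree-k nodes falls off approximately as

    C(k) ~ 1/k,

and this curve is widely read as evidence of *hierarchical modularity*:
dense modules nested inside sparser super-modules. spokenet implements the
machinery for the parsimonious alternative: the 1/k law is generated by a few
**super-hubs** — nodes whose degree far exceeds the structural cutoff
√(N·kmin) of the degree distribution — combined with **hub–hub repulsion**,
the simple-graph constraint that any node pair shares at most one edge.

The quantitative core is a closed-form triangle expectation. A newly added
node of degree `k_j` in a network with `M` edges and mean degree `⟨k⟩`
attaches to a degree-`k_i` node with capped edge multiplicity
`m(k_i, k_j) = min(k_i·k_j / 2M, 1)` and creates

    ΔN(k_i) = k_i · m(k_i, k_j) · m(k_j, ⟨k⟩)

expected new triangles through it. Below the regime boundary
`k* = 2M / k_j` this grows as `k²` (flat C(k) contribution); at and above
`k*` the multiplicity saturates and ΔN grows as `k`, which is exactly a
`C(k) ~ 1/k` contribution. Injecting super-hubs into a *completely
unstructured* random graph therefore bends a flat spectrum into the
"hierarchical" one — no hierarchy involved.

The package provides:

* **Graph core** — tidy edge-table graphs, triangle counts, per-node
  clustering, C(k) spectra, degree assortativity (`as_edge_table()`,
  `ck_spectrum()`, `assortativity_coefficient()`, …).
* **Generators** — the deterministic hierarchical model (5^L nodes),
  power-law configuration graphs, preferential-attachment super-hub
  injection, and the spoke model of hub repulsion.
* **Null models** — degree-preserving rewiring, exact joint-degree-matrix
  seeds, and a simulated-annealing null matched to the real triangle count
  (`anneal_to_triangle_count()`), plus partially frozen overlapping nulls.
* **Profiles** — correlation profiles against rewired ensembles, C(k) null
  envelopes, and CCDF-based super-hub detection.
* **Analytics** — the closed-form theory (`expected_new_triangles()`,
  `predicted_ck()`, `required_neighbor_edges()`) and log–log slope fits with
  broom-style `tidy()`/`glance()` methods.
* **Co-expression** — missingness filters and correlation-threshold network
  construction for expression matrices.
* **Synthetic data** — generators for power-law, assortativity-targeted,
  modular and block-correlated-expression fixtures.

Everything is tidyverse-shaped: data frames in, tibbles out, `autoplot()`
methods for result objects.

## Worked example

Inject two degree-2,000 super-hubs into an uncorrelated 10,000-node graph
with P(k) ~ k^−2.6 and watch the flat C(k) turn into 1/k:

```r
library(spokenet)

ex <- experiment_superhub(n = 10000, gamma = 2.6,
                          hub_degrees = c(2000, 2000), seed = 42)
ex
#> <superhub_experiment>
#>   baseline: n = 10000, M = 8389, triangles = 30
#>   injected hubs: 2000, 2000 (regime boundary k* = 8.4)
#> # A tibble: 5 × 5
#>   quantity      slope std_error r_squared n_points
#>   <chr>         <dbl>     <dbl>     <dbl>    <int>
#> 1 ck_baseline -0.0827    0.117     0.0134       39
#> 2 ck_after    -0.866     0.0232    0.967        49
#> 3 dn_all       1.28      0.0361    0.966        46
#> 4 dn_capped    1.02      0.0442    0.937        38
#> 5 dn_uncapped  1.66      0.0449    0.996         8
```

Three things to read off the slopes: the baseline C(k) of the uncorrelated
substrate is flat (−0.08 ± 0.12); after injection the triangle gain ΔN(k)
scales linearly (slope 1.02) in the capped regime k ≥ k\*, as the theory
predicts; and the post-injection clustering spectrum `ck_after` declines with
slope ≈ −0.9, i.e. C(k) ~ 1/k from hub injection alone.

The impossibility argument in one line — for a degree-253 node to carry the
network-average clustering of 0.21, its neighbours would need

```r
required_neighbor_edges(253, 0.21)
#> [1] 6694
```

edges among themselves, more than many complete networks contain.

The hierarchical counter-model is available for comparison; note how weak its
degree anticorrelation is:

```r
g6 <- hierarchical_model(6)
length(graph_nodes(g6)); nrow(g6)
#> [1] 15625
#> [1] 64866
assortativity_coefficient(g6)
#> [1] -0.0768
```

See `vignette("superhub-scaling")` for the methods: regime-restricted slope
fitting, the annealing schedule, profile calibration, and the limits of the
synthetic generators.

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "spokenet", load_package = "installed")'
```

The suite includes brute-force oracle checks (dense adjacency-matrix algebra
against the fast igraph/C++ routes on 100+ random graphs) and
`tests/testthat/test-acceptance.R`, which re-derives every headline number at
full problem size.

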