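---
title: "Methods: super-hubs, hub repulsion, and the 1/k clustering law"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-hubs, hub repulsion, and the 1/k clustering law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
set.seed(1)
```

```{r load}
library(spokenet)
library(ggplot2)
```

## The question

In many biological networks the mean clustering coefficient of degree-k nodes,
C(k), falls off roughly as 1/k. A popular reading of this curve is that the
network is *hierarchically modular*: small dense modules combine into larger,
sparser ones, and the C(k) ~ 1/k law is the fingerprint of that architecture.

spokenet implements the machinery needed to test a competing, much more
parsimonious explanation: the law is produced by a handful of **super-hubs** —
nodes whose degree far exceeds the structural cutoff of the degree
distribution — together with the constraint that a simple graph allows at most
one edge between any two nodes (**hub–hub repulsion**). No hierarchy is
required; injecting super-hubs into an entirely unstructured random graph
bends a flat C(k) into 1/k.

This vignette documents the models, estimators, and numerical choices. All
problem sizes below are this package's own defaults, chosen to make each
effect measurable on a laptop-scale budget.

## Graphs as tidy edge tables

Every function takes a plain data frame whose first two columns are edge
endpoints, and returns tibbles. `as_edge_table()` canonicalises input: ids
become character, self-loops are dropped, duplicate edges (either orientation)
collapse, endpoints are ordered lexicographically, rows are sorted. All
derived statistics are therefore invariant to row order and edge orientation.

```{r edge-table}
as_edge_table(data.frame(a = c("b", "a", "c"), b = c("a", "b", "c")))
```

Clustering conventions: a node of degree k with N triangles through it has
clustering coefficient 2N / (k (k − 1)). Nodes of degree < 2 have no defined
value and are excluded from every clustering statistic. `ck_spectrum()` is
always computed on exact degrees; logarithmic binning, where wanted, is a
presentation-layer choice.

## The deterministic hierarchical model

`hierarchical_model(levels)` builds the classic counter-example architecture:
level 1 is a five-clique; each subsequent level replicates the current module
four times and wires every bottom-level peripheral node of the replicas to the
root centre. The result has exactly 5^L nodes and follows the edge recursion
E(L) = 5 E(L − 1) + 4^L.

```{r hier}
g2 <- hierarchical_model(2)
length(graph_nodes(g2))
nrow(g2)
node_clustering(g2, nodes = graph_nodes(g2)[1])
```

This model genuinely produces a declining C(k), but its degree assortativity
at L = 6 is only ≈ −0.077 — far weaker than the hub repulsion of real
biological networks, which is one of several reasons the hierarchy reading is
not forced by the data.

## Closed-form triangle expectations

The analytical core is small enough to state in full. For a network with M
edges and mean degree ⟨k⟩, a newly added node of degree k_j attaches to a node
of degree k_i with expected *capped* edge multiplicity

m(k_i, k_j) = min(k_i k_j / 2M, 1),

the cap encoding that a simple graph permits one edge per pair. The expected
number of triangles the new node creates through node i is

ΔN(k_i) = k_i · m(k_i, k_j) · m(k_j, ⟨k⟩).

Two regimes follow, split at **k\* = 2M / k_j**:

* k_i < k\* (multiplicity below cap): ΔN ∝ k_i², so the clustering
  contribution 2ΔN / (k_i (k_i + 1)) is degree-independent — a flat C(k);
* k_i ≥ k\* (multiplicity capped at 1): ΔN ∝ k_i, so the contribution decays
  as 1/k — the observed law.

`theory_context()`, `edge_multiplicity()`, `expected_new_triangles()` and
`predicted_ck()` expose these formulas; `required_neighbor_edges()` gives the
companion impossibility argument — e.g. a degree-253 node would need
`required_neighbor_edges(253, 0.21)` = 6694 edges among its neighbours to
sustain the network-average clustering of 0.21, more than many whole networks
contain.

## The simulation experiment

`experiment_superhub()` runs the whole pipeline:

1. draw n = 10,000 degrees from P(k) ∝ k^−2.6 truncated at the structural
   cutoff √(n·kmin) (`sample_powerlaw_degrees()`), and realise them as a
   random simple graph by stub matching (`configuration_graph()`);
2. record the baseline C(k), which is flat because the graph is uncorrelated;
3. inject super-hubs by preferential attachment (`inject_superhubs()`) —
   2 nodes of degree 2,000 for the linear regime, or 200 nodes of degree 20
   for the quadratic regime;
4. measure per-node triangle gains (`measure_delta_triangles()`) and fit
   log–log slopes (`fit_loglog_slope()`).

A deliberate estimator choice: the ΔN(k) slope is fitted **within each
theoretical regime**, with the boundary k\* = 2M/k_hub computed from the
graph, not estimated from the data. Fitting across the regime boundary mixes
the k² and k laws and biases the slope; restricting the fit to k ≥ k\* (for
the degree-2,000 hubs) or to k < k\* (for the degree-20 hubs, whose cap is
never reached) recovers the predicted exponents. `glance()` on the experiment
reports the slopes of both regimes plus the whole-range fit, so the choice is
auditable.

```{r superhub, eval = FALSE}
ex <- experiment_superhub(n = 10000, gamma = 2.6,
                          hub_degrees = c(2000, 2000), seed = 1)
glance(ex)   # slope_dn_capped ~ 1, slope_ck_after ~ -1, baseline ~ 0
```

## Null models

Three degree-aware nulls, in increasing order of constraint:

* `rewire_degree_preserving()` — double-edge swaps; preserves the exact
  degree sequence. Ten successful swaps per edge decorrelate edge placement.
* `joint_degree_seed()` — per-degree-class stub matching; preserves the full
  joint degree matrix (and therefore the assortativity) exactly.
* `anneal_to_triangle_count()` — a Metropolis walk started from a
  joint-degree seed whose moves exchange endpoint pairs of **equal degree**
  between two edges, the minimal move preserving the joint degree matrix. The
  energy is E = |N_random − N_real| / N_real, the relative triangle-count
  mismatch, and proposals are accepted with probability min(exp(−ΔE/T), 1).

The annealing schedule exposed by the defaults (t0 = 0.05, geometric cooling
every 1,000 steps) was chosen on the scale of the energy quantum: one triangle
changes E by 1/N_real, so useful temperatures are a few of those quanta —
large enough to escape the greedy floor, small enough to converge in ~10^6
proposals on a 500-node modular graph. Setting `t0` near zero gives a pure
greedy descent (monotone energy); `log_proposals = TRUE` records (ΔE,
accepted) pairs so the Metropolis rule itself can be audited.

The purpose of the annealed null is the key negative control: a random graph
matched to *both* the joint degree matrix and the total triangle count — i.e.
"as modular as the real network" — still shows the same C(k) decline, so the
decline cannot be evidence of modularity.

`overlapping_null()` freezes a random subset of edges before rewiring, for
nulls that must retain a fraction of real structure.

## Correlation profiles and super-hub detection

`correlation_profile()` bins endpoint degrees into base-2 octaves, counts
edges per bin pair, and compares them with a 100-member rewired ensemble:
`ratio` = observed / ensemble mean, `z` = deviation in ensemble standard
deviations. `hub_hub_ratio()` pools the entire high-degree corner (all bin
pairs with both endpoints in the upper half of occupied bins) before taking
the ratio: single-bin tail counts are Poisson-noisy, and the pooled statistic
is what cleanly separates hub repulsion (< 1, e.g. the `spoke_graph()` model,
where hubs never touch) from hub affinity (> 1, e.g. assortative
co-expression-like graphs).

`detect_superhubs()` makes the "degree far beyond the cutoff" judgment
reproducible. It fits the bulk exponent by least squares on the **log–log
complementary cumulative distribution** (slope = 1 − γ) — the CCDF is
monotone and robust to the empty and single-count degrees that flatten a raw
histogram fit — then flags tail degrees whose expected occupancy n·P(K ≥ k)
under the fitted law falls below `alpha` (default 0.05). It is a
tail-probability heuristic, not a hypothesis test, and both knobs are exposed.

## Co-expression networks

`coexpression_network()` connects gene pairs whose Pearson correlation over
pairwise-complete arrays strictly exceeds 0.65 in absolute value (strong
anticorrelation also counts). Pairs sharing fewer than 3 arrays are never
connected. `filter_expression()` applies the two standard missingness filters
in a fixed order — first arrays with more than 10 % missing entries, then
genes missing in more than 7 of the remaining arrays — and records exactly
what it removed in attributes. The gene filter is an absolute count because
that is how such thresholds are usually specified for a fixed array panel; it
is exposed as an argument.

Thresholded co-expression graphs are the canonical *assortative* counterpoint
to protein and metabolic networks: correlation is transitive enough that
hub–hub edges are enriched rather than suppressed, which the profile tools
make visible.

## Synthetic data

The generators used throughout the tests are first-class exports:

* `synth_metabolic_like()` — power-law bulk plus injected super-hubs;
* `synth_correlated_graph()` — greedy degree-preserving swaps toward a target
  assortativity (negative emulates hub repulsion, positive emulates
  co-expression);
* `synth_modular()` — planted-partition graphs whose triangle surplus far
  exceeds any degree-matched null, the annealing test-bed;
* `synth_expression()` — block-correlated expression via a shared latent
  factor per module, √ρ·factor + √(1−ρ)·noise, with independent missingness.

These are deliberately minimal mechanisms: they reproduce the statistics the
methods consume (degree tails, mixing, triangle surplus, block correlation,
missingness) and nothing else. They are not biophysical models; in particular
`synth_expression()` has homogeneous within-module correlation and
`synth_modular()` has no degree heterogeneity inside modules.

## Numerical notes and limitations

* All randomised functions take an optional `seed`; `NULL` uses the ambient
  RNG stream, and seeded calls restore the stream afterwards.
* Stub matching occasionally cannot place the last few stubs of a heavy-tailed
  sequence; leftovers are dropped with a warning (in practice ≥ 99 % of nodes
  get their exact degree). Erdős–Gallai infeasible sequences are an error.
* Log–log slope fits drop zero values (they cannot be log-transformed) and
  can filter points by per-degree support via `min_count`.
* The triangle-expectation theory assumes an uncorrelated substrate; applied
  to strongly assortative graphs its regime boundary is only approximate.
* The annealed null matches the *count* of triangles, not their placement;
  two graphs with equal energy can differ in where the clustering sits.
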