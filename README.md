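# lwcent

Identifying the influential nodes of a network — the ones whose activation
spreads furthest — is a basic problem in network science, epidemiology and
viral marketing. Global centralities (betweenness, closeness) rank well but
cost too much on large graphs; plain degree is cheap but coarse. `lwcent`
implements a **multiple-local-attributes weighted centrality (LWC)** that
stays local (O(n) once neighbourhoods are enumerated) while combining four
per-node attributes:

* degree `k_i` and clustering coefficient `clc_i = 2 e_i / (k_i (k_i − 1))`
  (direct, one-hop influence),
* two-hop degree `thk_i` — the number of *distinct* nodes within distance 2
  of `i` (duplicate neighbours counted once), and the two-hop clustering
  coefficient `thclc_i = Σ_{j∈N(i)} clc_j` (indirect influence).

The node-by-attribute decision matrix is normalized per attribute
(`d_ij = x_ij / max_i x_ij`, then `r_ij = d_ij / Σ_i d_ij`), each attribute
receives an entropy weight

```
E_j = −(ln n)⁻¹ Σ_i r_ij ln r_ij ,     w_j = (1 − E_j) / Σ_j (1 − E_j) ,
```

so attributes whose distribution across nodes is more concentrated (lower
Shannon entropy, more discriminating) weigh more, and every node is scored
`LWC_i = Σ_j w_j r_ij` and ranked descending with tie-aware dense ranks.

The package also ships everything needed to *evaluate* such rankings:

* baseline centralities: degree, betweenness, closeness, local centrality,
  clustered local degree, clustering coefficient;
* a discrete-time SIR Monte-Carlo spreading oracle (infection probability
  β per contact, recovery probability γ = 1 by default; a node's influence
  is its mean outbreak size over repeated simulations), with a principled
  default β = 1.5 × ⟨k⟩/(⟨k²⟩−⟨k⟩);
* ranking metrics: monotonicity M(S), score CCDFs, Kendall τ-a against the
  SIR ground truth, the imprecision function ε(p), and top-T Jaccard
  similarity;
* Erdős–Rényi / Barabási–Albert generators and named toy fixtures, GML and
  edge-list readers, and a command-line front end.

All per-node results are tibbles keyed by node label, so everything
composes with dplyr/ggplot2; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

```r
library(lwcent)

fit <- lwc(toy_graph("triangle_tail"))   # edges 1-2, 1-3, 2-3, 3-4, 4-5
fit
#> LWC ranking of 5 nodes
#> entropy weights: k=0.0501, thk=0.0274, clc=0.5799, thclc=0.3425
#> # A tibble: 5 × 3
#>   node    score  rank
#>   <chr>   <dbl> <int>
#> 1 1     0.355       1
#> 2 2     0.355       1
#> 3 3     0.242       2
#> 4 4     0.0397      3
#> 5 5     0.00844     4
```

On this tiny graph the clustering coefficient is the most discriminating
attribute (lowest entropy), so it carries 58% of the weight and the two
triangle nodes 1 and 2 share the top rank ahead of the hub node 3.

Evaluating methods against the SIR ground truth on a 200-node scale-free
graph:

```r
ev <- evaluate_methods(generate_ba(200, 2, rng_seed = 1),
                       methods = c("degree", "cc", "localc", "lwc"),
                       beta = "auto", runs = 100, rng_seed = 3)
ev
#> SIR-based evaluation (beta = 0.2504, gamma = 1, runs = 100, seed = 3)
#> # A tibble: 4 × 3
#>   method monotonicity kendall_tau
#>   <chr>         <dbl>       <dbl>
#> 1 degree        0.504       0.449
#> 2 cc            0.991       0.71
#> 3 localc        0.999       0.736
#> 4 lwc           0.990       0.449
```

`monotonicity` is 1 when every node gets a unique rank (degree's 0.50
reflects its heavy ties); `kendall_tau` is the τ-a correlation between each
ranking and the mean-outbreak-size ranking. A Barabási–Albert graph has
almost no triangles, so here the entropy weighting concentrates on the
near-degenerate clustering columns and LWC does not beat the global
methods; on networks with substantial clustering the four attributes are
all informative (see the methods vignette for this trade-off).

`autoplot(ev, type = "imprecision")`, `"jaccard"` and `"ccdf"` draw the
corresponding comparison curves.

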