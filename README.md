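# hyperlouvain

Generative clustering of hypergraphs in R. Many interaction data sets —
group conversations, committee memberships, co-purchases, browsing
sessions — join *sets* of nodes, not pairs. `hyperlouvain` models such data
with a **degree-corrected hypergraph stochastic blockmodel (DCHSBM)**:
every unordered node tuple `R` receives hyperedges as an independent
Poisson draw with rate

```
b_R * prod(theta[i], i in R) * Omega(z_R)
```

where `theta` are per-node degree propensities, `z` are cluster labels,
`b_R` counts the orderings of `R`, and the symmetric affinity function
`Omega` depends on the edge's cluster composition only through its
partition vector `p = phi(z_R)` (sorted label multiplicities). Approximate
maximum-likelihood inference in this model yields a family of hypergraph
**modularity** objectives

```
Q(z) = sum_p [ cut_p(z) log Omega(p) - vol_p(z) Omega(p) ]
```

and, for the all-or-nothing (AON) affinity, the size-resolved form
`-sum_k beta_k [ cut_k(z) + gamma_k sum_l vol(l)^k ]` with
`beta_k = log(omega_k1 / omega_k0)` and
`gamma_k = (omega_k1 - omega_k0) / beta_k` — a direct generalization of
dyadic modularity with a resolution parameter per edge size. The package
provides:

* a hypergraph data model with plain-text readers/writers, c-core
  extraction and edge-size filtering (`hypergraph()`,
  `read_hyperedge_list()`, `c_core()`, `restrict_edge_size()`);
* partition vectors, the AON / group-number / relative-plurality /
  pairwise affinity families, and closed-form conditional ML estimation of
  `theta` and `Omega` (`estimate_theta()`, `estimate_omega()`,
  `aon_params()`);
* exact likelihood decomposition and fast generalized cuts/volumes
  (`dchsbm_loglik()`, `cut_p()`, `vol_p()`, `symmetric_modularity()`,
  `aon_modularity()`);
* Louvain-style maximum-likelihood inference: the general symmetric
  variant and the fast AON variant with supernode collapse, wrapped in a
  coordinate ascent that alternates partitioning with parameter estimation
  (`symmetric_hmll()`, `aon_hmll()`, `fit_dchsbm()`,
  `refine_partition()`);
* exact DCHSBM samplers and the planted-partition benchmark generators
  (`sample_dchsbm()`, `sample_two_block()`, `sample_runtime_testbed()`,
  `detectability_threshold()`);
* dyadic baselines — normalized/unnormalized clique projection and graph
  maximum-likelihood Louvain (`clique_project()`, `gmll()`);
* evaluation: adjusted Rand index, BIC-based comparison of affinity
  families, and experiment harnesses (`ari()`, `dchsbm_bic()`,
  `compare_affinities()`, `run_detectability_sweep()`,
  `run_runtime_benchmark()`).

## Worked example

Two planted communities of 250 nodes; every node has on average five
2-edges and five 3-edges. Half of the 2-edges are within-community (pure
noise), 95% of the 3-edges are within-community — so the usable signal
lives entirely in the higher-order edges:

```r
library(hyperlouvain)

samp <- sample_two_block(n = 500, p2 = 0.5, p3 = 0.95, seed = 42)
samp$H
#> Hypergraph: 500 nodes, 2097 distinct hyperedges (total weight 2103)
#>   edge sizes: m_2=1298, m_3=805

fit <- fit_dchsbm(samp$H, family = "aon", alternations = 20,
                  regularize = TRUE, seed = 1)
fit
#> DCHSBM fit (aon): 2 clusters, log-likelihood -15043.3 (best of 20 alternations)
ari(fit$labels, samp$z)
#> 0.952

fit$aon
#>   k      beta        gamma       omega0       omega1
#> 1 2 0.1110519 5.163924e-05 4.882498e-05 5.455962e-05
#> 2 3 4.1035089 5.843773e-09 4.026703e-10 2.438265e-08
```

The fitted size weights tell the story: `beta_2 ~ 0.11` (the model has
learned that 2-edges are nearly uninformative) while `beta_3 ~ 4.1` (a
within-cluster 3-edge is ~e^4 times likelier than a split one). The
recovered partition agrees with the planted one at ARI 0.95. The dyadic
baseline on an unnormalized clique projection does worse with the same
budget:

```r
G <- clique_project(samp$H, normalized = FALSE)
gfit <- gmll(G, alternations = 20, regularize = TRUE, seed = 2)
ari(gfit$labels, samp$z)
#> 0.861
```

Affinity families can be compared at a fixed labelling by BIC (lower is
more plausible):

```r
compare_affinities(samp$H, fit$labels)
#>    family    loglik kappa      bic
#>        gn -15043.30     4 30117.21
#>       aon -15043.30     6 30132.51
#>  pairwise -15043.30     6 30132.51
#>        rp -15964.41     6 31974.72
```

With two clusters and edges up to size 3, the group-number family fits
exactly as well as AON with fewer parameters, and Pairwise coincides with
AON (for edges of size at most 8 the two families split partition vectors
identically) — ties like these are structural, not numerical accidents.

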