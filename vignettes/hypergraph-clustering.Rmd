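---
title: "Generative hypergraph clustering with hyperlouvain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative hypergraph clustering with hyperlouvain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperlouvain)
```

## The model

Many relational data sets — group conversations, committee memberships,
co-purchases, co-browsing sessions — are hypergraphs: each interaction joins
an arbitrary set of nodes rather than a pair. `hyperlouvain` clusters such
data under a degree-corrected hypergraph stochastic blockmodel (DCHSBM).
Each node $i$ carries a cluster label $z_i \in \{1,\dots,\bar\ell\}$ and a
degree propensity $\theta_i \ge 0$. For every unordered node tuple $R$
(repeated nodes allowed), the number of hyperedges placed on $R$ is an
independent Poisson draw

$$a_R \sim \mathrm{Poisson}\!\big(b_R \,\pi(\theta_R)\,\Omega(z_R)\big),$$

where $b_R$ is the number of distinct orderings of $R$,
$\pi(\theta_R)=\prod_{i\in R}\theta_i$, and the *affinity function* $\Omega$
maps the cluster composition of the tuple to a non-negative rate factor.
We work throughout with symmetric affinities: $\Omega$ depends on $z_R$
only through the *partition vector* $p = \phi(z_R)$, the non-increasing
profile of label multiplicities in the edge (e.g.
$\phi(1,1,4,1,2,3,2) = (3,2,1,1)$). Four parametric families are built in:

* **AON** (all-or-nothing): only distinguishes whether the edge lies fully
  inside one cluster ($\|p\|_0 = 1$); one pair $(\omega_{k1}, \omega_{k0})$
  per edge size $k$.
* **GN** (group number): one value per (size, number of distinct groups).
* **RP** (relative plurality): distinguishes whether the gap between the
  two largest groups in the edge is below $k/4$.
* **Pairwise**: distinguishes whether the number of ordered discordant node
  pairs in the edge, $k^2 - \sum_j p_j^2$, is below $k(k-1)/4$.

For edges of size at most 8 the Pairwise rule splits partition vectors
exactly as AON does (the smallest discordant-pair count of a split edge,
$2(k-1)$, already exceeds $k(k-1)/4$ when $k \le 8$), so the two families
define the same model there and differ only on larger edges. This shows up
as ties in model comparison and is expected.

## Estimation

With $z$ fixed, the conditional maximum-likelihood estimates are closed
form: $\hat\theta = d$, the observed degree vector (under the volume
normalization $\sum_i \theta_i \delta(z_i,\ell) = \mathrm{vol}(\ell)$), and
for each affinity class $Y$

$$\hat\omega_Y \;=\;
\frac{\sum_{p \in Y} \mathrm{cut}_p(z)}{\sum_{p \in Y} \mathrm{vol}_p(z)},$$

where $\mathrm{cut}_p$ is the weighted count of observed edges with
composition $p$ and $\mathrm{vol}_p$ sums $\prod_j \mathrm{vol}(y_j)$ over
all ordered label tuples with composition $p$. `vol_p()` evaluates these
sums from the power sums $S_q = \sum_\ell \mathrm{vol}(\ell)^q$ through an
inclusion–exclusion recursion over assignments of parts to distinct
clusters, so the cost depends on the number of parts, not on $\bar\ell$ or
on $\bar\ell^k$ enumeration; `vol_p_update()` refreshes a value after a
move in $O(k)$. These estimates are exact when clusters have equal volumes
and are otherwise the standard approximation; no correction is attempted.

Two numerical conventions matter. First, classes observed zero times get a
pseudocount (`smoothing`, default $10^{-10}$) added to their numerator so
that log-affinities stay finite; set `smoothing = 0` to disable. Second,
$0\cdot\log 0 = 0$: a zero-affinity class contributes nothing when no
observed edge falls in it.

## Objectives and optimizers

Dropping terms constant in $(z, \Omega)$, the log-likelihood splits as
$L = Q + K + C$ with the modularity term

$$Q(z, \Omega) = \sum_p \big[\mathrm{cut}_p(z)\,\log \Omega(p)
  - \mathrm{vol}_p(z)\,\Omega(p)\big].$$

The expectation part deliberately sums over *all* node tuples, including
those with repeated nodes — that is what makes $\sum_\ell
\mathrm{vol}(\ell)^k$ exact, and the package works in ordered-tuple space
throughout, validated against a brute-force tuple-enumeration oracle in the
tests. Under the AON family the objective collapses to

$$Q_{\mathrm{AON}}(z) = -\sum_k \beta_k\big[\mathrm{cut}_k(z)
  + \gamma_k \textstyle\sum_\ell \mathrm{vol}(\ell)^k\big] + \text{const},
\qquad
\beta_k = \log\frac{\omega_{k1}}{\omega_{k0}},\quad
\gamma_k = \frac{\omega_{k1}-\omega_{k0}}{\beta_k},$$

a direct generalization of dyadic modularity with a size-resolved
resolution parameter: restricted to $k = 2$ its differences across
partitions match classical resolution-modularity differences. The strict
hypergraph modularity ($\beta_k = 1$, $\gamma_k = m_k/\mathrm{vol}(H)^k$)
is available via `strict_modularity_params()`.

Two Louvain-style ascent algorithms optimize these objectives:

* `symmetric_hmll()` handles any symmetric affinity. Because a move changes
  each incident edge's full partition vector, the hypergraph is never
  collapsed; later rounds move previously formed clusters as units over the
  full incidence data.
* `aon_hmll()` exploits the AON structure: only the indicator
  "edge inside one supernode" and the edge's original size matter, so
  clusters are collapsed into consolidated supernodes between rounds and
  identical reduced edges are merged. This is the scalable path.

Both use the same control flow — a node-level round, then collapse/set
rounds until a round accepts no move — the same strict acceptance rule
($\Delta Q > 0$ with a $10^{-12}$ float guard, no epsilon threshold), and
the same tie-breaks (stay put on ties; otherwise the lowest-labelled
candidate cluster). Candidate targets are the clusters adjacent through
some incident hyperedge. Visit order is a fresh random permutation per pass
(`visit = "random"`, seeded) or deterministic (`visit = "sequential"`, used
to check that the two paths coincide move-for-move under AON affinities).
The returned partition admits no improving whole-cluster move into an
adjacent cluster; with disassortative parameters ($\beta_k < 0$) a
non-adjacent merge can in principle still gain through the volume term,
which the edge-guided move set does not explore — agglomerative ascent is
inherently a poor fit for disassortative structure.

An optional regularizer $-n\log\bar\ell$ (a uniform label prior) is added
to the move objective with `regularize = TRUE`; a move that empties a
cluster then gains $n\log\frac{\bar\ell}{\bar\ell-1}$. It is off by
default and used in the detectability experiments, where the true number of
clusters is small.

## Coordinate ascent and its initialization

`fit_dchsbm()` alternates the z-update (the matching Louvain optimizer,
warm-started from the previous partition unless `cold_start = TRUE`) with
closed-form re-estimation of $(\hat\Omega, \hat\theta)$, and returns the
alternation with the highest log-likelihood — penalized by $-n\log\bar\ell$
when `regularize = TRUE`, so that selection and optimization use the same
objective. Warm-started alternations stop early at an exact fixed point:
once neither the partition nor the estimate changes, every further
alternation is provably identical. If an alternation yields a single
cluster, the cross-class estimates are undefined and the previous
parameters are retained for the next z-update.

The starting point deserves care. A greedy ascent launched from singletons
under a-priori assortative parameters can only bootstrap along 2-edges:
size-$k$ edges contribute no gain until $k-1$ of their nodes are already
together. When 2-edges are uninformative or disassortative, round-one
merges follow noise, the supernode collapse makes the mixing irreversible,
and re-estimation from the mixed partition cannot recover the per-size
signal signs. We verified that the move evaluation is not at fault: with
oracle parameters and an informative start the optimizer recovers planted
structure that the singleton start misses entirely. The default
initialization therefore bootstraps from the dyadic side: short regularized
fits on both clique-projection variants (normalized and unnormalized; a
collapsed arm is retried without the penalty), scored by the
cluster-count-penalized hypergraph likelihood — plain likelihood
systematically favours fragmented candidates — and the winner seeds both
the first z-update and the first parameter estimate. This mirrors the
observation that a dyadic pass followed by hypergraph refinement is
stronger than either alone. `dyadic_init = FALSE` restores the bare
strict-modularity start (symmetric families then start from a
density-calibrated assortative table $\Omega_0(p) =
(m_k/\mathrm{vol}(H)^k)\,e^{1-\|p\|_0}$).

`refine_partition()` runs the same ascent from a user-supplied partition,
e.g. to refine a graph-Louvain solution; `gmll()` is the dyadic baseline
itself, implemented as the $k=2$ specialization of the AON ascent on a
projected graph, with real-valued projected weights flowing through the cut
and volume formulas as a Poisson quasi-likelihood and a single adaptively
estimated resolution. Its `criterion = "modularity"` variant returns the
max-modularity alternation instead of the max-likelihood one.

## Samplers and what they emulate

* `sample_dchsbm()` draws exactly from the model: per (size, affinity
  class), a Poisson total at the closed-form class rate, each edge placed
  by i.i.d. $\theta$-proportional node draws with rejection to the class —
  never $\Theta(n^k)$ tuple enumeration. Repeated-node tuples are produced
  (as the model allows) unless `allow_repeats = FALSE`.
* `sample_two_block()` is the detectability design: $n = 500$ nodes in two
  communities of 250, mean per-node 2- and 3-degrees $c_2 = c_3 = 5$,
  within fractions $(p_2, p_3)$; per-size edge counts are Poisson with mean
  $n c_k / k$. The within cluster is chosen uniformly (communities are
  equal-sized, so the distinction from size-proportional choice is
  immaterial here); between-cluster edges are uniform over node sets
  spanning both communities, by rejection.
* `sample_runtime_testbed()` is the scalability design: $n/200$ equal
  clusters, exactly $m = 10n$ edges, sizes uniform on $\{2,3,4\}$, each
  edge within one uniformly chosen cluster with probability $p_k$;
  `fig1 = TRUE` sets the sparse-large-edge regime $p_2 = 3/5$,
  $p_3 = 1/n^3$, $p_4 = 1/n^4$.

These generators produce unit-weight, distinct-node edges with homogeneous
degrees within clusters; they do not emulate heavy-tailed degrees,
multi-edges, or size-degree correlations found in real data, so passing
recovery tests on them demonstrates correctness of the machinery under the
stated designs, not performance on any empirical data set.
`detectability_threshold(ci, co)` evaluates the dyadic planted-partition
signal $(c_i-c_o)^2 / (2(c_i+c_o))$, detectable only above 1.

## Model comparison

`dchsbm_bic(H, z, family)` scores a family at a fixed labelling by
$\kappa\log m - 2\hat L$ with $m$ the total weighted edge count (the
Poisson observations; `sample_size = "nodes"` switches the convention) and
$\kappa$ the affinity parameter count: $2\bar k$ for AON/RP/Pairwise,
$\sum_{k\le\bar k}\min(k,\bar\ell)$ for GN (the cap on group counts can be
lifted with `restrict_groups = FALSE` in `count_parameters()`). The $n$
degree parameters are identical across families and excluded. Note the
AON–Pairwise identity above: on data with $\bar k \le 8$ their BICs tie
exactly, and the comparison table lists AON first on ties.

## Sizes used in the test suite

The automated checks run at desk scale, chosen to exercise every code path
while keeping the suite fast: exhaustive oracles up to $n = 8$ nodes and
$\bar\ell, k \le 5$; likelihood brute forces on 100 random instances with
$n \le 6$; recovery at the study design $n = 500$ with 20 replicate seeds;
model recovery at $n = 400$ with five planted clusters and sizes up to 5.
Runtimes of the benchmark harness are reported, never asserted.

## Known limitations

* The closed-form estimates (and hence the modularities) are exact only for
  equal cluster volumes; with very unbalanced clusters the fitted
  resolutions are biased toward balance.
* Greedy ascent offers no global guarantee; disassortative planted
  structure is recovered unreliably at best.
* The symmetric path operates on full incidence data and is intended for
  moderate instances; only the AON path scales.
* The c-core extraction removes hyperedges touching a removed node whole
  (rather than truncating them to the surviving nodes), preserving
  hyperedge semantics; the truncating alternative would yield denser cores.
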