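# hubtrace

Topological analysis of protein–protein interaction (PPI) networks with a
focus on finding *key regulators*: the high-degree hubs that remain embedded
in triangle motifs at the deepest level of the network's community
hierarchy. The package is aimed at systems-biology work on disease
interactomes — networks assembled from interaction databases whose
structure (scale-free degree distribution, hierarchical modularity,
assortative mixing) carries information about which genes hold the network
together and what happens when they are silenced.

## What it computes

**Topology.** The six standard measures as functions of degree *k*: the
degree distribution *p(k) = n_k / N*; the local clustering coefficient
*c_i = 2 m_i / (k_i (k_i − 1))* averaged per degree class; neighborhood
connectivity *C_N(k)* (mean neighbor degree); and closeness, eigenvector
and betweenness centralities (*C_C*, *C_E*, *C_B*), computed per connected
component with endpoint-excluding betweenness.

**Scaling fits.** The degree distribution is fitted as a discrete power law
*p(k) ∝ k^(−γ)* by exact maximum likelihood with the lower cutoff `x_min`
chosen to minimize the Kolmogorov–Smirnov distance, and a semi-parametric
bootstrap goodness-of-fit p-value (default 2500 replicates; p ≥ 0.1 means
the power law is plausible). The other five measure-versus-degree profiles
are fitted by log–log least squares. Exponent signs follow one convention:
positive means the quantity decays with *k*. From the six fits the network
is classified hierarchical scale-free (decaying *p(k)* **and** *c(k)*),
plain scale-free (decaying *p(k)*, flat *c(k)*), or left unclassified; the
sign of the *C_N(k)* slope gives assortativity.

**Key regulators.** Hubs (degree ≥ a configurable floor) are traced through
iterated, seeded Louvain modularity maximization: each hub-containing
community is recursively split until it reaches a triangle motif G(3,3),
loses cohesion, or stops improving modularity. Hubs whose trace ends inside
a motif are *motif-localized*; those whose motif lies at the deepest level
are the *key regulators*. Each key regulator's grip on its community is
quantified by the edge share `P_KR(x[s]) = x[s] / N[s]` per level *s*.

**MCODE.** A re-implementation of the Bader–Hogue molecular complex
detection algorithm (k-core-based vertex weighting, seed-and-grow
complexes, haircut post-processing) used to noise-filter drug-associated
genes through high-scoring dense complexes (score = density × size ≥ 10 by
default).

**Knockout resilience.** Motif-localized hubs are eliminated cumulatively,
one hierarchy level at a time, and all six scaling fits are recomputed
after each step — the degradation of the clustering exponent tracks the
network's shift away from hierarchical organization.

**Synthetic networks.** Seeded generators with planted ground truth: the
deterministic Ravasz–Barabási hierarchical construction, preferential
attachment, discrete power-law samplers, and `planted_hub_hierarchy()` —
nested stochastic-block shells with a planted hub triangle whose recovery
by the pipeline is exactly testable.

## Worked example

```r
library(hubtrace)

gen  <- planted_hub_hierarchy(rng_seed = 42)   # ~4,000-node preset
net  <- gen$network
tree <- decompose_network(net, hub_threshold = gen$truth$hub_floor,
                          rng_seed = 42)
tree
#> hierarchy tree: 3965 nodes, 18462 edges; depth 3
#> 3 hub(s) at degree >= 44 ; 1 motif leaf(s)

key_regulators(tree)
#> [1] "C1_H1" "C1_H2" "C1_H3"

pkr_profile(tree, net, "C1_H1")
#>   level  x n_edges        p_kr
#> 1     0 52   18462 0.002816596
#> 2     1 22    5737 0.003834757
#> 3     2  4     272 0.014705882
#> 4     3  2       3 0.666666667
```

The three planted hubs are recovered as key regulators, and the trace shows
the defining signature: the hub carries a vanishing share of the whole
network's edges (0.3%) but two-thirds of its terminal motif's — its share
grows monotonically with depth.

```r
deg <- igraph::degree(net)
fit_powerlaw_mle(deg[deg > 0], n_boot = 250, rng_seed = 42)
#> power-law fit [mle_ks] of 'p': exponent 3.0555, x_min 8, gof 0.0534, p = 0.000 (n = 2069)
```

The fitted tail exponent is ~3.06; the bootstrap p-value of 0 honestly
reports that this block-structured synthetic network is *not* a literal
power law — on a pure power-law sample (`powerlaw_samples()`) the same
routine recovers the exponent within ±0.1 and returns p-values well above
0.1.

The whole pipeline — topology, hierarchy, MCODE filter, knockout,
resultant network — runs as one call and writes its stage artifacts
(TSV/JSON) plus a summary:

```r
res <- run_pdn_analysis(run_config(rng_seed = 42, out_dir = "out"))
res$summary$key_regulators
#> [1] "C1_H1" "C1_H2" "C1_H3"
```

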