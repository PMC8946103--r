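---
title: "Methods: hierarchical topology, hub tracing and knockout resilience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical topology, hub tracing and knockout resilience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, decision rules and numerical choices
behind `hubtrace`, in the order the pipeline applies them.

## The data model

A network is a simple undirected graph over opaque, case-sensitive node
identifiers (gene symbols, typically). Self-loops and duplicate edges are
removed on ingestion and their counts reported; no gene-symbol
normalization is attempted — synonym resolution belongs upstream of this
package. Isolated nodes are first-class citizens: knocking out a hub keeps
its orphaned neighbors in the graph with degree zero, so "network size" is
unambiguous across a knockout trajectory, while degree-profile fits exclude
the zero-degree class (its log is undefined and it carries no scaling
information).

## Topological measures

Six measures are computed, all standard: the degree distribution
$p(k) = n_k/N$; local clustering $c_i = 2m_i/(k_i(k_i-1))$, defined as 0
for $k_i < 2$ but excluded from degree-binned profiles (the ratio is
undefined there, and a log-scale fit cannot use zeros); neighborhood
connectivity $C_N(k)$, the mean degree of a node's neighbors averaged over
each degree class; closeness $C_C = n/\sum_j d_{mj}$ with the sum over the
$n$ other members of the node's connected component; eigenvector
centrality, the non-negative principal eigenvector of the largest
component's adjacency matrix scaled to unit Euclidean norm; and
betweenness $C_B(i) = \sum_{j<k} g_{jk}(i)/g_{jk}$ with endpoints
excluded, optionally normalized by $(n-1)(n-2)/2$ per component.

Closeness and betweenness are computed per connected component so that
disconnected inputs carry no infinities; the networks this pipeline
targets are connected, so the choice only affects degenerate inputs.
Degree binning uses exact degree classes, no logarithmic binning — on the
graph sizes involved the exact classes keep the fits reproducible and the
unit tests crisp.

## Power-law fitting

Two routes, chosen by what the data are:

* **Discrete maximum likelihood with KS model selection** for the degree
  *sample* (one integer per node). For each candidate lower cutoff
  `x_min` — the unique sample values up to the 80th percentile, keeping at
  least 10 tail points — the tail exponent maximizes the exact discrete
  likelihood with the Hurwitz-zeta normalizer, and the candidate with the
  smallest Kolmogorov–Smirnov distance between empirical and fitted tail
  CDFs wins. The goodness-of-fit p-value is semi-parametric bootstrap:
  synthetic datasets draw their tail from the fitted model and their body
  from the empirical data below `x_min`, are refitted from scratch, and
  the p-value is the fraction whose KS distance reaches the observed one.
  2500 replicates by default (tests run scaled-down replicates, noted
  below). The percentile cap on `x_min` keeps enough tail to fit; ties in
  the KS comparison count against the model, which makes the p-value
  conservative.
* **Log–log least squares** for the five measure-versus-degree profiles,
  which are means, not distributions — a KS bootstrap is not defined for
  them. Zero-valued bins are dropped with a message; fewer than 3 usable
  bins is an error rather than an extrapolation. The reported statistic
  is the maximum absolute log-space residual, and the slope's standard
  error is kept alongside as the fit's uncertainty band.

One sign convention everywhere: the exponent is positive when the quantity
*decays* with degree. Assortativity is read directly from the sign of the
fitted $C_N(k)$ slope (negative exponent = increasing profile =
assortative mixing).

**Numerics.** The Hurwitz zeta $\zeta(s,a)$ is computed by 64 direct terms
plus an Euler–Maclaurin tail (three Bernoulli corrections), accurate to
~1e-14 over the exponent range of interest. The discrete power-law sampler
inverts the exact CDF over a tabulated support up to $10^6$; the residual
tail mass (about $10^{-8}$ for the exponents used) falls back to the
continuous approximation
$\lfloor (x_{min}-\tfrac12)(1-u)^{-1/(\alpha-1)}+\tfrac12 \rfloor$.

## Topology classification

A network is **hierarchical scale-free** when both $p(k)$ and $c(k)$ decay
(exponent above the flat band) with acceptable fit quality, **scale-free**
when $p(k)$ decays but $c(k)$ is flat within the band, otherwise
**unclassified**. Fit quality means KS statistic (or max log residual)
at most `gof_max = 0.33` and, when a bootstrap p-value is present, at
least `p_min = 0.1`.

The flat band defaults to **0.25 absolute exponent units**. This value was
chosen from the behavior of the two reference constructions the classifier
must separate: finite preferential-attachment networks — the canonical
scale-free null — show a residual $c(k)$ slope of roughly 0.2 (their
clustering is not exactly degree-independent at $n = 5000$), while the
hierarchical signature is a slope near 1. A much tighter band would brand
the scale-free reference "hierarchical-ish"; a looser one would swallow
genuine hierarchy. The band is an explicit threshold argument, so any
other convention is one keystroke away.

Classification is a pure function of the six stored fits and the
thresholds: re-running `classify_topology()` on a summary's own fits
reproduces its class. It is also monotone in `gof_max` — loosening the
quality gate can only add classifications, never remove them.

When a network's degree distribution is a deterministic lattice (the
Ravasz construction, for instance), the KS bootstrap compares it against a
smooth power law and rightly rejects; for classification of such
constructions the bootstrap is skipped (`n_boot = 0`), leaving the KS
distance itself as the quality gate.

## Hierarchical decomposition and key regulators

Louvain modularity maximization is applied recursively. The root (level 0,
the whole network) is split; every resulting community that contains at
least one hub is split again, and so on. Recursion stops at a community
when it is a triangle motif G(3,3), has fewer than 3 nodes or 3 edges,
when Louvain finds no improving split, or at the level cap. A community of
3 nodes and 2 edges is a terminal leaf but *not* a motif — G(3,3) is read
strictly as the triangle. Hub-free communities are retained as leaves
(the analysis traces hubs, not the full tree); `decompose_all = TRUE`
decomposes everything for diagnostics.

Louvain's result depends on its sweep order, so the order is made explicit:
vertices are sorted by id and shuffled by a seeded RNG before each call,
and every community split draws a deterministic seed from the tree's base
seed. Given `(network, seed)` the whole tree, every trace and every
modularity value are byte-reproducible. The resolution parameter stays at
1; the nested structure emerges from re-running Louvain *within*
communities, where the smaller edge total makes finer structure visible —
the same resolution limit that hides submodules at the root reveals them
one level down.

A hub is **motif-localized** when its trace terminates inside a triangle
motif (membership required — being co-clustered next to a motif does not
count). **Key regulators** are the motif-localized hubs whose motif lies
at the deepest motif level reached by any hub. Their per-level edge share
$P_{KR}(x^{[s]}) = x^{[s]}/N^{[s]}$ (own degree inside the level-$s$
community over that community's edge count) lies in $(0,1]$ and, for a
genuine key regulator, grows strictly with depth.

Hub selection: an explicit degree floor, or a quantile mode (top fraction
of the degree distribution) for networks of different scale. Level
numbering starts at 0 for the whole network; reports that prefer 1-based
presentation can add one.

## MCODE

The Bader–Hogue algorithm re-implemented: vertex weight = (order of the
highest k-core of the *closed* neighborhood's induced subgraph) × (density
of that core); nodes under the degree cutoff weigh 0. Complexes grow from
unassigned seeds in decreasing weight order (ties broken by node id, which
makes the node-disjoint assignment deterministic), absorbing unassigned
neighbors whose weight is at least $(1 - \text{node score cutoff})$ times
the seed's, within the BFS depth cap. Post-processing discards complexes
lacking a 2-core (checked against the requested `k_core`) and haircuts
members with fewer than two in-complex connections; fluff is off — the
stringent parameter set used throughout is haircut on, degree cutoff 2,
node score cutoff 0.2, K-core 2, depth 100. Scores are density × size on
the final member set; drug-associated genes are kept when they sit in any
complex scoring at least 10. Raising the score floor can only shrink the
filtered set.

## Knockout experiment

Motif-localized hubs are grouped by the level of their deepest motif and
removed one group per step, cumulatively, re-running the full topology
summary on each survivor graph. The order is explicit configuration —
shallow-to-deep (default), deep-to-shallow, or a window restricted to
levels 3–6 — because level bookkeeping conventions differ between
analyses; all orders remove the same union and reach the same final graph.
Isolated survivors stay in the graph but out of the fits; a fit that loses
support (too few usable bins) is recorded as absent, never extrapolated.
Trajectories default to `n_boot = 0` — recomputing a 2500-replicate
bootstrap per step would dominate runtime without informing the
exponent trajectory, which is the quantity of interest.

## The synthetic generator and what it does (not) show

`planted_hub_hierarchy()` builds the study networks: background stochastic
blocks on a density gradient (degree decay and assortative mixing), one
chain of nested community shells per planted motif depth, and one hub
triangle per chain. The construction is engineered so that modularity
optimization probably-correctly reproduces the planted structure:

* at every level, a hub's edges into the continuing shell exceed its edges
  into any single sibling block, while each block pull stays below the
  block's modularity mass penalty — so hubs descend the chain;
* hub wiring targets are disjoint across the three hubs and restricted to
  the best-connected nodes of each block — a node with two hub edges, or
  one weakly homed, would follow the hubs and end as a pendant fused to
  the triangle, corrupting the motif;
* downward glue between shells reaches only the next level, so the small
  inner shells are not degree-inflated past the hub floor;
* the declared hub floor is the midpoint between the largest non-hub
  degree and the smallest hub degree, and the generator refuses to emit a
  network where that separation failed.

Free-standing dense blocks play the role of drug-gene-rich protein
complexes for the MCODE stage; `annotate_drug_genes()` flags a fraction of
their members plus background noise.

What passing tests on these networks show: the pipeline's machinery —
tracing, motif detection, key-regulator selection, complex detection,
knockout bookkeeping — does what it claims on networks whose ground truth
is known. What they do not show: that any real interactome satisfies the
generator's assumptions (independent block edges, a single planted
triangle per chain, clean degree separation between hubs and the rest).
Real PPI networks have correlated edges, overlapping complexes and hubs at
every depth; on such data the pipeline reports what it finds, with no
recovery guarantee.

## Problem sizes used by the test suite

Chosen to keep the default run comfortably inside a few minutes of one
CPU while leaving every statistical margin intact: oracle comparisons on
200 random graphs of up to 30 nodes (50 for the eigenvector check);
maximum-likelihood recovery at $n = 10^4$ over 20 seeds; bootstrap
plausibility at 250 replicates (a tenth of the analysis default) over 10
datasets of $n = 5000$; planted-recovery over 50 seeds of the ~4,000-node
preset; knockout properties over 10 seeds; exhaustive-partition modularity
checks up to 8 nodes (4,140 partitions).

## Known limitations

* Louvain is a heuristic: on small graphs its modularity is within 0.02 of
  the exhaustive optimum in the test battery, but no global guarantee
  exists, and the decomposition inherits its stochasticity (tamed, not
  removed, by seeding).
* The bootstrap p-value inherits the discreteness of the KS statistic on
  small supports; it is conservative rather than exact.
* The resultant network is built as an induced subgraph of the analyzed
  network — it cannot introduce interactions absent from the input, unlike
  workflows that re-query interaction databases for the selected genes.
* Only triangle motifs terminate the hierarchy; no general motif census is
  attempted.
* MCODE here scores unweighted graphs; edge-confidence-weighted variants
  are out of scope.
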