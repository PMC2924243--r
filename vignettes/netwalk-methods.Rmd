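---
title: "Data-biased random walks for context-specific network retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-biased random walks for context-specific network retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netwalk)
```

## The problem

Given a genome-scale interaction network (protein-protein, signaling,
TF-target and functional-similarity edges) and one vector of strictly
positive per-gene ratio values per condition (e.g. treated/control mRNA
ratios), we want a relevance score for *every node and every interaction*
that reflects how coherently the data and the local wiring point at the
same neighbourhood — without pre-selecting a focus gene list and without
rewarding genes merely for being hubs.

## The model

A random walker moves over the network with transition probabilities biased
by the data. For node $i$ with downstream neighbour set $N_i$ (undirected
edges count both ways),

$$p_{ij} = \frac{w_j}{\sum_{k \in N_i} w_k}, \qquad j \in N_i,$$

so the walker prefers neighbours with high data values. Nodes with no
downstream neighbours (dangling nodes) transition uniformly to all $n$
nodes. With restart probability $q$ and restart distribution $r$, the
visitation vector is the unique fixed point of

$$g \leftarrow (1 - q)\, g P + q\, r,$$

found by power iteration from the uniform start $g^0_i = 1/n$. With biased
restart (the default) $r_i = w_i / \sum_k w_k$, which biases the process to
the data a second time; with uniform restart $r_i = 1/n$. Because the
update is a contraction with factor $(1-q)$, the fixed point is unique for
any $q > 0$ and the error on exit is bounded by $\mathrm{tol}\,(1-q)/q$.

Visitation frequencies of a walk on any real network correlate strongly
with degree, so the raw $g$ mostly reports hubness. We therefore run a
second, *background* walk with every $w_i = 1$ (whose biased restart is
then uniform) at the same $q$, and report

$$g'_i = g_i / g_{r,i},$$

the relative visitation frequency: the data-driven score with the purely
topological expectation divided out.

Interactions are scored by **Edge Flux**: the probability mass flowing
through an arc at stationarity, $e_{ij} = g_i\, p_{ij}$, normalized against
the background flux of the same arc,

$$s_{ij} = \log_2 \left( e_{ij} / e_{r,ij} \right).$$

$s$ is centered at 0; positive values mean more mass than topology alone
would put through the interaction (coherently *high* data values around
it), negative values coherently low values. The whole distribution of $s$
is the result: subnetworks of any size can be read off it with any cutoff.

Before the walk the pipeline (i) flips directed TF$\to$target edges so that
target-gene measurements inform the transcription factor's score rather
than the reverse, and (ii) winsorizes the data at the interpolated 0.1st
and 99.9th percentiles so single outliers cannot dominate the transition
probabilities. Genes present in the network but missing from the data are
imputed to 1, the "no change" ratio.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `q` | 0.01 | restart probability per step (dimensionless). Small values keep the walk diffusive; the default biases gently while guaranteeing ergodicity. |
| `bias_restart` | TRUE | restart $\propto w$ rather than uniform. |
| `tol` | 1e-12 | L1 convergence tolerance of the power iteration. |
| `max_iter` | 10000 | iteration cap; non-convergence warns and flags the result. |
| `winsorize` | TRUE | clip at 0.1/99.9 percentiles before the walk. |
| FS `threshold` | 0.001 | annotation-overlap significance below which a functional-similarity edge is created. |

`tol = 1e-12` is affordable because the sparse iteration costs
$O(\text{edges})$ per step: a 14,500-node / 188,000-edge run completes in a
few seconds on one CPU with a transition matrix of under 5 MB.

## Functional-similarity edges

Two genes that never touch physically can still act in the same process
(e.g. enzymes of one metabolic pathway), so indirect edges increase the
usable gene coverage. Given flat gene-term annotations, the overlap score
for genes $i, j$ sharing term set $N$, with $G_k$ the carriers of term $k$
and $n$ the gene universe, is

$$s_{ij} = \prod_{k \in N} \frac{\binom{|G_k|}{2}}{\binom{n}{2}},$$

the probability that a uniformly drawn gene pair co-carries every shared
term. A term carried by all genes contributes a factor of 1 (uninformative);
rare shared terms drive the product to 0. An FS edge is created when
$s_{ij} < 0.001$. Genes co-annotated to the same *metabolic* pathway are
additionally connected pairwise; signaling pathways are excluded from the
pathway rule because their interactions are already in the network as
direct edges. The formula sits behind one pure function
(`fs_significance()`) with a brute-force pair-enumeration test, so the
transcription is independently checkable. The universe $n$ defaults to the
number of annotated genes and is configurable; annotations are used as
supplied, with no propagation up the ontology graph.

## Design choices where the design was open

* **Normalization form.** $s = \log_2(e/e_r)$: a ratio on the familiar
  gene-expression log2 scale, exactly 0 when data equal the background,
  and antisymmetric between coherent up- and down-neighbourhoods.
* **Undirected-edge reporting.** Flux is an arc-level quantity; an
  undirected edge has two arcs. Both are retained (`e_fwd`, `e_rev`) and
  the reported per-interaction score combines them by summation *before*
  normalization, so one number per drawn edge results.
* **Background run.** Uses the same $q$ as the foreground run —
  normalization must compare like with like.
* **Dangling nodes.** Implemented as an implicit rank-one correction
  (uniform row $1/n$) so the matrix stays sparse; their outgoing mass
  corresponds to no real interaction and is excluded from the edge table
  but included in conservation checks.
* **Winsorize before impute**, over observed values only, so imputed 1s
  cannot distort the percentiles.
* **Duplicate records.** The same gene pair under different interaction
  types is kept once per type (scores are reported per typed interaction
  record); exact duplicates merge. Undirected edges are stored once with
  lexicographically ordered endpoints and expanded to two arcs only at
  matrix-build time.
* **Ward clustering** of the edges-by-conditions $s$ matrix uses
  `hclust(method = "ward.D2")` — Ward's minimum-variance criterion on
  Euclidean distances — on raw $s$ values without standardization, since
  $s$ is already on a common centered scale across conditions. Rows are
  the union over conditions of each condition's top-$k$ and bottom-$k$
  interactions; $k$ is a user parameter.
* **Directionality conflicts** between records from different sources are
  not reconciled: each record is treated independently.
* **SIF files** carry no directedness flag, so on read the directedness
  defaults by interaction type (TF_TARGET and SIGNALING directed, PPI and
  FS undirected). The 4-column TSV dialect is lossless and is the default.
* **q = 0** is allowed for limit-case studies but warns: without restart
  the stationary distribution need not be unique on periodic or
  disconnected graphs.

## The synthetic generators

`make_planted_fixture()` is the package's test bed. It emulates the
situation the method is built for: a hub-rich (preferential-attachment)
background network — hubs are exactly what topology normalization must
control for — with two densely wired planted modules, one up-regulated
around ratio 4 and one down-regulated around 0.25, log2 noise SD 0.25,
against a background of no-change genes (defaults: 1000 nodes, 25-gene
modules, 3 attachment edges per node, within-module wiring probability
0.35, seed 42). Per-condition activation patterns support multi-condition
clustering experiments. Ground-truth module edge sets are exported with
every fixture.

`make_toy_network()` is a fixed 12-node illustration: a 6-node ring
cluster G–L (value 2) bridged to a high-value node A (value 5) at G and L,
with a background clique B–F (value 1) spoked to every cluster node. The
topology is documented in one constant; tests against it assert rankings,
never exact values, so the illustration cannot silently anchor numerics.
Cluster-internal edges are deliberately fewer than a quarter of all edges
so "cluster edges occupy the top quartile of $s$" is a falsifiable claim.

What the generators do *not* emulate: measurement error structure of real
microarrays (probe effects, normalization artifacts), correlated noise
along pathways, literature bias in edge discovery beyond the degree
distribution, or annotation incompleteness. Passing the planted-recovery
tests therefore demonstrates algorithmic correctness and topology-bias
control, not end-to-end biological validity on real data.

## Numerical notes and degenerate inputs

* Convergence is declared on L1 change < `tol`; the fixed-point residual
  on return is below $10\,\mathrm{tol}$ and the distance to the exact
  solution below $\mathrm{tol}(1-q)/q$ (confirmed against a dense direct
  solve of $g(I - (1-q)P) = q r$ to L$\infty$ $\le 10^{-10}$ on random
  graphs up to 200 nodes).
* Percentiles use type-7 linear interpolation between order statistics;
  with small samples the 99.9th percentile interpolates between the two
  largest values, so winsorization shrinks (not removes) a lone spike.
* Ranking ties in subnetwork extraction break lexicographically by
  (source, target, itype) and are logged.
* Fewer than 2 observed data values: winsorization is skipped with a
  warning. Empty data vectors impute to all-1 and return the background
  identity ($g' \equiv 1$, $s \equiv 0$). Empty networks error at
  matrix-build time.
* An all-equal Edge Flux matrix cannot be clustered and collapses to a
  single cluster with a warning.

Test-suite problem sizes were chosen to exercise every code path while
keeping the whole suite fast on one CPU: oracle comparisons on up to
200-node graphs, property and recovery tests on 120-1000-node fixtures,
perturbation curves on the 1000-node default fixture (levels 0-0.75, five
replicates), and one 14,500-node / ~188,000-edge run asserting the sparse
storage contract.

## Known limitations

* $s$ has no significance calibration: it ranks interactions but carries
  no p-value.
* Gene identifiers are plain strings; no identifier mapping is provided,
  so network, data and annotations must share a vocabulary.
* TF-edge reversal is a single-application transform; `netwalk()` manages
  it, but calling `reverse_tf_edges()` twice undoes it.
* The method scores interactions in a *given* network; it does not infer
  novel edges, and its output is bounded by the network's coverage.
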