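---
title: "Detecting protein complexes by seed-and-extend growth under a density-modularity fitness"
author: "ppicomplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes by seed-and-extend growth under a density-modularity fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppicomplex)
options(ppicomplex.verbose = FALSE)
```

## The problem and the model

A protein complex is a group of proteins that physically interact to carry
out a cellular function. In a protein-protein interaction network (PPIN) —
an undirected graph with proteins as nodes and detected interactions as
edges — complexes appear as subgraphs that are *dense* (members interact
richly with each other) and/or *modular* (members interact little with the
rest of the network). High-throughput interaction data are noisy: many
recorded edges are false positives, and methods that trust the raw topology
inherit that noise. `ppicomplex` addresses both issues: it first reweights
every edge with evidence that the two endpoints really work together, then
grows candidate complexes greedily from reliable seeds under a fitness
function that rewards density and modularity jointly, so complexes of
either character can be found.

### Edge weighting

Two independent signals are combined per edge $(v,u)$:

* **Common neighbours.** $CN(v,u) = \sqrt{|N(v)\cap N(u)|^2 / (|N(v)|\,|N(u)|)}$,
  where $N(\cdot)$ is the adjacency set. Proteins in one complex tend to
  share interaction partners, so a high common-neighbour fraction supports
  the edge. $N(v)$ is the full adjacency set (it includes $u$), so
  $|N(v)|$ is simply the degree; the common neighbours themselves never
  include the endpoints.
* **Annotation similarity.** With $GO(v)$ the set of Gene Ontology terms
  annotating $v$ (term identifiers are compared as opaque strings; the
  ontology graph is never traversed),
  $GO(v,u) = |GO(v)\cap GO(u)| \,/\, \max(\min(|GO(v)|,|GO(u)|),\, \overline{GO})$
  when the intersection is non-empty and 0 otherwise. The floor
  $\overline{GO}$ — the average term count over the network's annotated
  proteins — penalises similarity that rests on very few annotations.
  For weighting, the BP and MF namespaces are the appropriate input; CC
  terms encode complex membership itself and are reserved for the
  enrichment read-out.

The edge weight is the arithmetic mean $w = (CN + GO)/2 \in [0,1]$. Edges
with $w = 0$ carry no topological or functional support, are treated as
noise, and are deleted; proteins left without edges are removed. The
average $\overline{GO}$ is computed once on the full loaded network before
any pruning. When no network protein carries annotations the weighting
degrades gracefully to the common-neighbour signal alone.

### Seed selection

Each node is scored once, $Score(v) = d_w(v)\cdot NGCC(v)$: its weighted
degree times its neighbourhood-graph clustering coefficient (the summed
weight of all edges among $\{v\}\cup N(v)$ divided by the pair count of
that set). High scores mark nodes sitting at the reliable, densely
interconnected centre of a putative complex. Nodes enter a queue in
non-increasing score order; scores are never recomputed during detection,
and ties are broken lexicographically by protein id so runs are
reproducible across platforms.

### Cluster fitness and growth

For a candidate subgraph $SG$ with weighted in-degree $d^{in}_w$ (internal
edge weights) and out-degree $d^{out}_w$ (boundary edge weights):

* density $D = d^{in}_w / \binom{|SG|}{2}$,
* modularity $M = d^{in}_w / (d^{in}_w + d^{out}_w)$,
* fitness $F = (D + M + \sqrt{DM})/3 \in [0,1]$.

The geometric-mean term rewards subgraphs that are dense *and* modular
while leaving either property alone able to drive growth, so complexes
with high density but low modularity (or vice versa) remain detectable.
An isolated unit-weight clique attains $F = 1$ exactly.

Growth from a seed alternates an **extend** and a **correct** phase until a
full pass changes nothing. The extend phase ranks boundary neighbours by
the average internal interaction weight $2 d^{in}_w / |SG|$ of the cluster
*after* the candidate addition and accepts the top candidate iff (i)
fitness strictly increases and (ii) the candidate's edge count into the
cluster exceeds the *expectation edge* $F(SG)\cdot|SG|$, both computed on
the cluster before the move; the phase ends the first time the top
candidate fails. The correct phase mirrors this for removals of inner
nodes (members with at least one outside neighbour). Every accepted move
strictly increases $F$, which bounds the number of moves and guarantees
termination; a pass cap (default 100, far above the 2-3 passes seen in
practice) is kept purely as a safety net and warns if ever reached.

After growth, clusters smaller than `min_size` (default 3) and exact
duplicates are discarded; survivors are filtered for redundancy in
non-increasing fitness order, keeping a complex only if its overlap score
with every complex already kept stays below `redundancy_threshold`
(default 0.8). Detected complexes may overlap — nodes are never removed
from the network — but a node inside a kept complex is skipped as a seed.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_size` | 3 | smallest complex reported; two-protein clusters are indistinguishable from single edges |
| `redundancy_threshold` | 0.8 | overlap score at or above which the less fit of two complexes is dropped |
| `removal_connectivity` | `"literal"` | direction of the correct-phase connectivity test (see below) |
| `omega` | 0.2 | overlap score at or above which a predicted and a reference complex count as matched |
| `alpha` | 0.01 | significance level for Bonferroni-corrected enrichment p-values |

All are dimensionless. The `omega` and `alpha` defaults are the values
conventionally used for these metrics in the complex-detection literature.

## Evaluation stack

* **Overlap score** $OS(p,g) = |p\cap g|^2/(|p||g|)$; matching at
  $OS \ge \omega$ is one-to-many in both directions ($N_{cp}$ predictions
  matched, $N_{cg}$ references matched), giving precision, recall and
  their harmonic mean (F-measure).
* **Size-weighted Jaccard.** Each predicted complex contributes its best
  Jaccard coefficient against the references, weighted by its size
  (`jaccard_i`); symmetrically for references (`jaccard_s`); `jaccard` is
  their harmonic mean. These credit partial overlap continuously and are
  less sensitive to the matching threshold.
* **Functional enrichment.** For each complex and each term annotating a
  member, the hypergeometric upper-tail probability of observing at least
  $k$ term carriers in a complex of size $C$ drawn from a network of $N$
  proteins containing $F$ carriers, computed with `stats::phyper`.
  Bonferroni correction is applied per complex over its tested terms
  (mirroring how enrichment web services correct per query); a global
  scope is available via `correction = "global"`. Summary bins count
  complexes with minimum corrected p below 1e-15, 1e-10, 1e-5 and `alpha`.

## The synthetic benchmark

`generate_planted_network()` emulates exactly the structure the detector
assumes: complexes as dense, modular, functionally coherent subgraphs.
Members of a planted complex are wired with probability `p_within = 0.9`
(resampled until each complex is internally connected — a disconnected
plant could never be recovered as one cluster and would make recovery
tests vacuous); all other pairs appear with `p_between = 0.02`. Each
complex owns `terms_per_complex = 3` private GO terms carried by each
member with probability `annotation_coherence = 0.9`; 40 background
proteins draw 2 terms each from a 20-term noise pool. A fifth of the
complexes share one protein with another complex, exercising overlap
handling. The default sizes (10 complexes of 4-8 proteins) were chosen
once to mirror the small complexes that dominate curated catalogues, and
yield networks of roughly a hundred proteins — large enough to contain
genuine structure, small enough that the whole recovery benchmark over 20
generator seeds runs in seconds.

What the generator does **not** emulate: the heavy-tailed degree
distribution of real interactomes, correlated false negatives from bait
selection, promiscuous hub proteins, or incomplete and biased GO
annotation. Passing the recovery benchmark therefore shows the pipeline
is internally sound under its own model assumptions, not that it attains
any particular accuracy on real interactome data.

```{r recovery}
gen <- generate_planted_network(planted_network_spec(rng_seed = 42))
wnet <- build_weighted_network(gen$network, gen$annotations)
res <- detect_complexes(wnet)
unlist(evaluate_complexes(res$complexes, gen$truth, omega = 0.25))
```

## Numerical and design choices

* **Degenerate clusters.** Density and modularity are 0/0 for a singleton
  and for a cluster without incident weight; both are defined as 0, hence
  $F(\text{singleton}) = 0$. This makes the first expansion from any seed
  well defined: any positive-weight neighbour raises $F$ above 0 and
  trivially passes the expectation-edge test.
* **No epsilons.** Weights are never rounded and acceptance tests use
  strict floating-point inequalities; the algorithm only compares sums of
  weights, and all adjacency structures are kept in lexicographic order so
  every sum is accumulated in a fixed order. Detection output is therefore
  byte-identical across input files that differ only in line order.
* **Tie-breaking.** Equal seed scores and equal growth priorities resolve
  lexicographically by protein id.
* **Correct-phase connectivity.** The removal test is implemented in two
  directions behind `removal_connectivity`. The `"literal"` default
  requires a removal candidate's in-cluster edge count to *exceed* the
  expectation edge — the same direction as the addition test, which is how
  the procedure is usually stated — although that direction preferentially
  removes well-connected nodes and reads like a copy of the add-phase
  condition; `"inverted"` requires it to be strictly below. The
  fitness-increase requirement dominates either way, and both settings
  leave every worked fixture in this package at the same final clusters.
* **Removal priority.** Candidates in both phases are ranked by the
  weight-average of the cluster *after* the move, keeping the two phases
  symmetric.
* **Redundancy rule.** The pairwise filter uses the overlap score with
  threshold 0.8 as a documented default; only exact duplicates are removed
  unconditionally.
* **Local optimality.** Growth stops when the top-priority candidate of a
  phase fails, matching the stated termination rule; on every worked
  fixture a brute-force scan confirms the returned cluster admits no
  single permitted improving move.

## Problem sizes used by the test suite

The formula oracle suite cross-checks every score against independent
naive implementations on 110 random graphs of up to 50 nodes; the
hypergeometric tail is checked against exhaustive subset enumeration for
all feasible parameter combinations up to a 12-protein universe; local
optimality is brute-forced on graphs of up to 12 nodes; recovery runs the
default generator over 20 seeds. These sizes were chosen so the full
suite completes in well under a minute while still exercising every code
path at meaningful scale.

## Known limitations

* Scores are computed once; the detector never rescores seeds after
  complexes are removed from consideration, by design.
* Annotation similarity is flat set overlap — no semantic similarity over
  the GO graph — so distinct but related terms contribute nothing.
* The greedy growth is locally optimal only with respect to single-node
  moves; it can absorb a well-attached pendant into an otherwise perfect
  complex (growth from such a pendant keeps it, since a node whose
  neighbours all lie inside the cluster is never a removal candidate).
* Pure R implementation: comfortable for networks of a few thousand
  proteins; very large interactomes (tens of thousands of nodes) will be
  slow.
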