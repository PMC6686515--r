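# ppicomplex

Seed-and-extend detection of protein complexes in protein-protein
interaction networks (PPINs), for computational biologists who have an
edge list of interactions, optionally a protein-to-GO-term annotation
table, and want a reproducible list of candidate complexes plus the
standard evaluation metrics against a gold-standard catalogue.

## Method

Interaction data are noisy, so every edge $(v,u)$ is first reweighted by
two independent signals and their arithmetic mean:

$$CN(v,u) = \sqrt{\frac{|N(v)\cap N(u)|^2}{|N(v)|\,|N(u)|}}, \qquad
GO(v,u) = \frac{|GO(v)\cap GO(u)|}{\max(\min(|GO(v)|,|GO(u)|),\,\overline{GO})}, \qquad
w = \frac{CN + GO}{2}$$

with $\overline{GO}$ the average annotation count over the network's
annotated proteins. Zero-weight edges are pruned as noise. Each node is
scored once as $Score(v) = d_w(v)\cdot NGCC(v)$ (weighted degree times
neighbourhood-graph clustering coefficient) and queued non-increasingly.
From each unvisited seed a cluster $SG$ grows by alternating extend and
correct phases under the composite fitness

$$F(SG) = \frac{D + M + \sqrt{D M}}{3}, \qquad
D = \frac{d^{in}_w}{\binom{|SG|}{2}}, \qquad
M = \frac{d^{in}_w}{d^{in}_w + d^{out}_w},$$

accepting a boundary move only if $F$ strictly increases and the moved
node's in-cluster edge count beats the expectation edge $F(SG)\cdot|SG|$.
Clusters below 3 members are discarded and near-duplicate complexes
(overlap score $\ge 0.8$) are filtered. Evaluation includes overlap-score
matching (precision/recall/F-measure at $\omega = 0.2$), size-weighted
Jaccard measures, and per-complex hypergeometric GO enrichment with
Bonferroni correction ($\alpha = 0.01$). A planted-complex generator
produces synthetic benchmarks with coherent annotations so the whole
pipeline is testable without downloads.

See `vignettes/detecting-protein-complexes.Rmd` for the full model,
parameter discussion and design choices.

## Worked example

```r
library(ppicomplex)

gen  <- generate_planted_network(planted_network_spec(rng_seed = 42))
wnet <- build_weighted_network(gen$network, gen$annotations)
#> build_weighted_network: kept 119/187 edges, 56/83 proteins
#>   (0 unannotated; Average(GO) = 2.446)

res <- detect_complexes(wnet)
#> detect_complexes: 18 seeds grown, 14 candidates (4 below size 3),
#>   12 complexes after redundancy filter

round(unlist(evaluate_complexes(res$complexes, gen$truth, omega = 0.25)), 4)
#> precision    recall f_measure       ncp       ncg jaccard_i jaccard_s   jaccard
#>    1.0000    1.0000    1.0000   12.0000   10.0000    0.9127    0.9623    0.9368

enrich_complexes(res$complexes, gen$annotations, igraph::V(wnet)$name)
#> <enrichment_result> 12 complexes, 12 significant at alpha = 0.01;
#>   mean min p_adj = 8.61e-06
```

The generator planted 10 complexes; all 12 detected clusters match a
planted complex at overlap score ≥ 0.25 (precision 1) and every planted
complex is recovered (recall 1); the size-weighted Jaccard of 0.94 says
the recovered memberships are near-identical, and every complex is
significantly enriched for its planted annotation terms.

On real data, start from files instead:

```r
net  <- read_edge_list("interactions.tsv")                       # idA<TAB>idB
ann  <- read_annotations("go.tsv", namespaces = c("BP", "MF"))   # id<TAB>term[<TAB>ns]
res  <- detect_complexes(build_weighted_network(net, ann))
write_complexes(res$complexes, "complexes.txt")                  # one complex per line
```

A command-line wrapper with `weight`, `detect`, `evaluate`, `enrich` and
`simulate` subcommands is installed at
`system.file("exec", "ppicomplex", package = "ppicomplex")`.

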