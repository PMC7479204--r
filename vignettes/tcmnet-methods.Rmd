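---
title: "Methods: bipartite herb–ingredient networks, modularity communities, and annotation-coherence validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite herb-ingredient networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmnet)
```

## The model

A curated traditional-medicine resource relates natural products (herbs) to
their chemical ingredients. `tcmnet` treats this relation as an unweighted
bipartite graph: herbs and ingredients are the two node sets, and each
recorded (herb, ingredient) incidence is one edge. Duplicate incidence rows
are collapsed — the data model is a binary incidence matrix, not a dosage or
abundance matrix. Side membership is tracked structurally (an internal side
tag on every vertex), so identifier strings never have to encode which side
an entity belongs to.

Minor disconnected fragments are typically curation artifacts, so analysis
operates on the giant component. Two unipartite projections follow: the
natural-product similarity network (NSN) joins two herbs when they share at
least one ingredient, and the ingredient similarity network (ISN) joins two
ingredients that co-occur in at least one herb. We weight each projection
edge by the number of shared opposite-side neighbors, computed as the
incidence matrix composed with its transpose with the diagonal removed.
The binary ("at least one shared neighbor") reading is the special case
`weighted = FALSE`, kept as a switch because the weighted projection is
strictly more informative and the binary one is recoverable from it.
Nodes that survive the giant-component stage but gain no projection edge
are retained as isolates rather than silently dropped.

Descriptive topology uses unweighted degrees: the degree of a node is the
number of links attached to it, and network heterogeneity is the square root
of the population variance of the degrees divided by their mean. A graph
whose nodes are all isolates has no defined heterogeneity and raises an
error rather than returning `NaN`.

## Community detection

Communities are found by greedy agglomerative modularity optimization.
Newman–Girvan modularity of a partition is

$$Q = \sum_c \left[ \frac{w_c}{W} - \left(\frac{s_c}{2W}\right)^2 \right]$$

with $W$ the total edge weight, $w_c$ the weight inside community $c$, and
$s_c$ the summed (weighted) degree of its members. `fast_greedy()` starts
from singleton communities and repeatedly merges the pair of connected
communities with the largest modularity gain $\Delta Q = e_{ij}/W - s_i
s_j/(2W^2)$, stopping when no merge has a positive gain; since $Q$ is
non-decreasing along the accepted merges, the final partition is the best
one encountered. Only connected pairs may merge, so disconnected components
are never fused. Merges are capped at $n-1$ and no resolution parameter is
introduced — plain Newman–Girvan $Q$ is the objective.

Determinism without a seed matters for reproducible pipelines, so ties in
$\Delta Q$ (compared within `1e-15`; merging stops when the best gain is
below `1e-12`, guarding against float noise around zero) are broken by the
lexicographically smallest pair of community labels, a community being
labelled by the smallest member id it contains. For the same reason, a tie
between equally large components in the giant-component stage is broken in
favor of the component containing the lexicographically smallest entity id.

Infomap, walktrap and other algorithms are deliberately *not*
reimplemented: they plug in through `register_partitioner()` and
`compare_partitions()` rescores every partition with the same
`score_modularity()` before averaging, so algorithms are ranked by mean
modularity on an equal footing — the comparison metric, not the external
algorithms, is the contribution here. Weighted modularity is the default
throughout; both modes are exposed and tested because published analyses of
this kind rarely state which was used.

## Annotation coherence and its null

Four annotation kinds are supported: herb meridian labels and herb property
labels (categorical sets), ingredient SMILES strings, and ingredient
protein-target identifier sets. For a partition and one annotation table,
every cluster with at least two annotated members receives the mean pairwise
similarity over its annotated members; entities without an annotation are
excluded from that validation only (never from clustering), and both
exclusions are reported.

Pairwise similarity must live in $[0,1]$ for the per-cluster means to be
comparable, so set-valued profiles use a normalized intersection. The
default is the overlap coefficient $|A \cap B| / \min(|A|,|B|)$ — the most
literal bounded normalization of "pairwise intersection" for sets of
unequal sizes — with Jaccard $|A \cap B| / |A \cup B|$ as a switch; every
report records which was used. Strings are compared with the Dice index
$2|T_a \cap T_b| / (|T_a| + |T_b|)$ over token sets; the default tokenizer
is the set of character bigrams, which requires no chemistry dependency.
The tokenizer is an explicit plug-in point, so users with a cheminformatics
stack can substitute real fingerprints without touching the rest of the
pipeline. A length-1 string tokenizes to itself so the index stays defined.
Internally all pairwise similarities for one annotation table are computed
at once from a sparse indicator-matrix cross product; this is exactly the
pairwise definition, just vectorized, and it makes the permutation null
cheap because replicates only reindex a precomputed matrix.

The null model asks: how similar would clusters of these same sizes be if
membership carried no information? Each replicate permutes the
entity-to-cluster assignment uniformly at random, preserving the multiset of
cluster sizes, and recomputes every per-cluster mean; the per-cluster means
from all replicates (default 100) are pooled into one null sample. Pooling
— rather than comparing per-replicate medians — mirrors how such null
distributions are usually displayed and compared as a single distribution
per annotation kind. The observed per-cluster means are then compared with
the pooled null by a two-sided, unpaired Wilcoxon rank-sum test: unpaired
because the two samples have different sizes ($k$ clusters vs $k \times$
replicates) and no natural pairing. The p-value is computed by exact
enumeration when the pooled sample has at most 12 values and no ties, and
otherwise by the normal approximation with tie and continuity corrections.
No multiple-testing correction is applied across the four annotation kinds;
all raw p-values are reported so users may correct as they see fit.

## The synthetic generator

`generate_dataset()` produces planted-block data that makes every stage
testable with known ground truth. Each of `n_blocks` blocks owns
`herbs_per_block` herbs and `ingredients_per_block` ingredients; each herb
draws `ingredients_per_herb` ingredients, from its own block's pool with
probability `1 - cross_block_rate` and otherwise from a uniformly chosen
foreign block. Each block also owns signature annotation sets (meridian,
property, target) and a signature SMILES-like motif string over a fixed
12-symbol alphabet of common SMILES characters — the strings exercise the
bigram tokenizer without pretending chemical validity. Entities inherit
their block's signatures; each label is then resampled uniformly with
probability `annotation_noise` and each string character mutated with
probability `string_mutation_rate`. A single RNG stream seeded once drives
all draws in a fixed documented order, so the same configuration always
yields byte-identical files.

Defaults — 3 blocks, 20 herbs and 30 ingredients per block, 6 draws per
herb, `cross_block_rate = 0.05`, `annotation_noise = 0.1` — describe a
small, clearly modular benchmark in which block recovery is expected but
not trivial (5% contamination occasionally pulls an individual herb into a
foreign community, which is why recovery is asserted as ARI ≥ 0.9 rather
than exact identity). Universe sizes follow the domain: 12 meridian labels
for the twelve classical channels, 9 property labels (on the order of the
four natures plus five flavors), 60 protein targets, 3 labels per
signature, and 20-character strings.

What the generator does *not* emulate matters for interpreting green tests:
real herb–ingredient data have heavy-tailed degree distributions (a few
promiscuous ingredients), overlapping and nested herb families rather than
clean blocks, annotation sets of widely varying size with systematic
missingness, and chemically structured SMILES. Passing tests therefore
demonstrate correctness of the algorithms and calibration of the statistics
under controlled conditions — not that any particular real dataset will
show coherent communities.

## Numerical and design choices

- Modularity is accumulated per community from edge sums; stored and
  recomputed values must agree to `1e-12`, which unit tests assert against
  both a first-principles evaluation of the $Q$ sum and `igraph`'s
  implementation.
- Entity ids are opaque strings; `"H####"`/`"I####"` zero-padded ids are a
  generator convention only, chosen to be deterministic, sortable and
  readable.
- Degenerate inputs fail loudly with typed conditions: empty incidence
  tables, edgeless graphs, partitions that do not cover the graph,
  all-singleton clusterings, and empty annotation payloads each have a
  dedicated error class.
- The pipeline funnels all randomness through the run seed: data generation
  uses it directly and each validation derives `seed + k` for its
  permutation stream, keeping reruns byte-identical while avoiding
  correlated draws across validations.
- The run configuration is a flat YAML key-value file; command-line flags
  override file keys. Artifacts follow a fixed layout (`incidence.tsv`,
  `nsn.tsv`, `isn.tsv`, `*_partition.csv`, `validation_*.json`,
  `report.json`).
- No minimum-ingredient filter is applied before projection and no small
  communities are pruned before validation; both are conceivable filters in
  published analyses of real data, but absent a stated rule the package
  applies none.

## Test problem sizes

The test suite exercises exact oracles at small scale and statistical
behavior at the generator's default scale: exhaustive-search modularity
oracles on graphs of up to 8 nodes (all set partitions enumerated),
brute-force projection oracles on random bigraphs of up to 50 + 50 nodes,
planted-block recovery and validation power over 100 generator seeds, and
type-I calibration of the full validation under annotation–partition
independence over 500 seeds at nominal $\alpha = 0.05$. These sizes were
chosen so the oracles stay exact and the Monte-Carlo error on the checked
rates stays a few percentage points.

## Known limitations

- Greedy agglomeration is a heuristic: on graphs whose optimum is not
  reachable by merges (long paths, rings) it returns less than the true
  maximum $Q$; tests assert it never exceeds the exhaustive optimum and
  attains it on modular fixtures.
- Modularity has a resolution limit; very small communities in very large
  networks may be absorbed. No resolution parameter is offered.
- The validation tests coherence of a partition that was *derived from the
  same incidence data* — significance means the communities align with
  external annotations, not that the partition is "correct".
- Hard (non-overlapping) clustering only; soft/overlapping membership and
  flow-based methods are out of scope by design, though their partitions
  can be scored via the registry.
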