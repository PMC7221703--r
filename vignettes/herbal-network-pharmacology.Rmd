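---
title: "Methods: layered network pharmacology with herbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered network pharmacology with herbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem and the data model

A medicinal herb is a mixture: tens to hundreds of chemical components, each
binding or modulating many protein targets, which in turn participate in many
signalling pathways and downstream clinical phenotypes. `herbnet` represents
this situation as a layered knowledge graph — node layers HERB, COMPONENT,
TARGET, PATHWAY, BIOPROCESS, PHENOTYPE — and implements the chain of
inferences a network-pharmacology study runs over it: phenotype association
by network propagation, mechanistic route ranking, pathway
over-representation, and comparative network analysis.

Edges are stored directed along the herb-to-phenotype cascade
(HERB→COMPONENT, COMPONENT→TARGET, TARGET→PATHWAY/BIOPROCESS/PHENOTYPE,
PATHWAY→PHENOTYPE) because that is the biologically meaningful reading of
each association, but every quantitative operation — degree, connectivity,
propagation — is direction-blind: an association database records that a
component and a gene are linked, not a flow direction. Node ids prefix the
layer (`"PATHWAY:Th17-Cell Differentiation"`) so a gene and a pathway with
the same string never collide, and so that layer information survives
formats like SIF that carry no attributes. Graphs are kept in canonical
sorted order, making loading order-independent and runs byte-reproducible.

The packaged fixture is the red-ginseng slice of this graph that can be
written down exactly: 5 signature components with their 37 unique target
genes, 9 signalling pathways with their member lists (degree sequence
11, 10, 10, 9, 9, 9, 8, 5, 4), and 4 clinical phenotypes. Two deliberate
storage decisions: the component→gene and pathway→gene lists are kept
verbatim as separate edge families even though their gene unions differ (the
pathway lists cover 35 of the 37 targets; FOS and JUN appear only on the
component side), and, because no per-phenotype target list is published
beyond a top-10 ranking, the fixture wires every target to every phenotype
uniformly and stores the top-10 ranking as an expected-output reference
table rather than as edges. Prose gene names are normalized to uppercase
HGNC-style symbols (TNF-α → TNF).

## Random walk with restart

Phenotype association uses the standard restart walk
$$F_{t+1} = \alpha\, F_t A + (1-\alpha)\, F_0,$$
with $A$ the row-normalized symmetric connectivity matrix and $F_0$ the
restart vector, uniform over the component-associated targets. Iteration
stops when $\lVert F_{t+1}-F_t\rVert_1 <$ `threshold`.

Numerical choices:

* **alpha = 0.7** by default: the walk keeps most mass within two or three
  steps of the start set, which matches the depth of the layered graph
  (target → pathway → phenotype); it is exposed as `rw.alpha`.
* **threshold = 1e-6 (L1), maxIter = 10000.** Convergence is geometric —
  the residual after $t$ steps is at most $2\alpha^t$, so at the defaults
  convergence needs only ~41 iterations and `maxIter` is a safety net, not
  a tuning knob. Non-convergence raises a typed error carrying the last
  residual.
* **Dangling nodes** get a unit self-loop before normalization. This keeps
  $A$ row-stochastic and hence every iterate a probability vector (mass
  conservation), without introducing teleportation edges that would change
  the topology.
* The exact fixed point solves $F(I-\alpha A) = (1-\alpha)F_0$; the system
  is nonsingular for $\alpha<1$. `rwrClosedForm()` is kept as an
  independent oracle and is cross-checked against the iteration in the test
  suite on random graphs.

**Raw vs normalized scores.** The notion of a "normalized" propagation score
is not standardized; `phenotypeScores()` reports both a raw converged score
and the raw score divided by the score the node receives under a
degree-proportional restart vector. The baseline quotient is a hub-bias
correction: it asks whether the start set reaches a phenotype *more than
generic connectivity alone would predict*. The two readouts answer different
questions, and the distinction matters for benchmarking: the synthetic
generator plants its phenotype signal as extra connectivity to
well-connected targets, which is precisely the kind of advantage the
baseline quotient is designed to discount. Recovery of a planted phenotype
is therefore assessed on the raw score, while the normalized score is the
right readout when asking which phenotype is *specifically* (rather than
promiscuously) associated. Isolated nodes get baseline weight 1, matching
their self-loop, so the quotient is always defined.

The walk treats the association network as undirected; a directed variant
would require flow-direction semantics the underlying databases do not
provide.

## Route exploration and the path score

Routes follow the three-layer template component → associated target →
endpoint, where the endpoint is the queried phenotype itself or a
pathway/bioprocess node adjacent to it (adjacency is direction-blind; in
the layer vocabulary, bioprocesses have no outgoing edge to phenotypes, so
the adjacency rule is what connects a terminal bioprocess to the query). An
optional four-layer template (component → target → pathway → phenotype,
requiring an explicit pathway→phenotype edge) is available via
`includePathway = TRUE`; three layers is the default because that is the
printed path format of the studies this pipeline supports.

Each route $r$ with nodes $v_1,\dots,v_n$ in a corpus of $N$ routes scores
$$\mathrm{score}(r) = \frac{1}{n}\sum_{i=1}^{n}
  \frac{\#\{\text{routes containing } v_i\}}{N},$$
the mean corpus frequency of its nodes: a route through recurrent hubs
scores near 1, an idiosyncratic route near $1/N$. The score is always in
$(0,1]$ and equals 1 iff every node occurs in every route. Frequencies are
computed within one phenotype's corpus, not across phenotypes — per-phenotype
corpora are what the downstream per-phenotype summaries consume — and this
is configurable simply by concatenating corpora before scoring. Ranking
keeps, per endpoint, the best-scoring route (ties resolved
lexicographically by node ids for determinism) and sorts by score
descending, ties lexicographic by endpoint label.

## Enrichment and consolidation

Over-representation of a query gene list in a pathway of $m$ genes, with
universe size $N$, query size $q$ and overlap $k$, is the upper-tail
hypergeometric probability $P(X \ge k)$ — identical to the one-sided
Fisher exact test. Choices:

* **Sidedness.** One-sided (over-representation); a two-sided test would
  also flag depletion, which is not what "enriched pathway" means here.
* **Universe** defaults to the union of all genes in the GMT collection —
  the sampling frame of the pathway database itself — and can be set to the
  graph's target set instead. Query genes outside the universe are dropped
  with a warning (on the fixture, FOS and JUN fall out this way because no
  pathway list contains them).
* **Filtering.** Only pathways with $k \ge 1$ are reported.
* **No multiple-testing correction by default**, since the downstream
  consolidation ranks primarily by overlap count and the conventional
  report is raw $p < 0.05$; Benjamini–Hochberg is available via
  `correction = "BH"`.
* **Consolidation** merges rows from several components or phenotypes by
  sorting on overlap descending, then $p$ ascending, then name, keeping the
  first row per pathway name. Ascending $p$ is an interpretive decision:
  ranking "top enriched" pathways requires the most significant first, and
  the alternative reading (least significant first) would contradict the
  purpose of the step. `topK()` truncates (default 100, the usual
  enriched-pathway report depth; per-phenotype summaries conventionally
  use 10).

One degenerate case worth knowing: on the packaged fixture the query (all
35 pathway-covered targets) equals the universe, so every $p$ is 1 — the
fixture pins down counts and degrees exactly but is too saturated to
exercise the statistics. Enrichment behaviour is therefore benchmarked on
synthetic graphs whose universe contains decoy genes.

## Network comparison

Per-phenotype pathway profiles are intersected COUNTIF-style
(`sharedPathways()`: pathways present in *all* phenotype lists), and two
herbs' shared sets are differenced (`exclusivePathways()`). Name matching is
exact-string after trimming and case-folding; no fuzzy matching, because a
principled similarity threshold for pathway names does not exist. Pathways
printed as "/"-separated groups are distinct nodes and are never merged.
The T-P network connects each target to the pathways containing it
(restricted to a target set, pathways without members dropped); the C-T-P
network adds the component→target edges. Degree ranking sorts a layer's
nodes by direction-blind degree, ties lexicographic.

## The synthetic generator

`generateGraph()` emulates the upstream databases the pipeline assumes —
a herb-component-target association resource and a pathway/phenotype
association network — at desk scale, with two planted, recoverable signals.
Defaults (chosen once, to mirror the fixture's scale):

| parameter | default | rationale |
|---|---|---|
| `nComponents`, `nTargets`, `nPathways` | 5, 40, 10 | fixture scale (5 components, 37 targets, 9 pathways) |
| `edgeProb` | 0.3 | fixture C-T density is 67/185 ≈ 0.36 |
| `pathwaySizeRange` | 5–15 | fixture pathway sizes span 4–11 |
| `plantedPathwayOverlap` | 8 | fixture pathway–target overlaps have median 9 |
| `plantedPhenotypeTargets` | 10 | length of a reported top-target list |
| `nPhenotypes`, `backgroundPhenotypeTargets` | 4, 3 | four clinical phenotypes; sparse background wiring |
| `nDecoyGenes` | 60 | pathway databases are much broader than one herb's target slice |

Component→target edges are independent Bernoulli draws, so the C-T edge
count is binomial and tests check concentration within four standard
deviations. One random pathway receives `plantedPathwayOverlap` genes from
the query set (the targets hit by at least one component); one random
phenotype is wired to the `plantedPhenotypeTargets` targets with the most
component connections. The ground-truth record names both plants (`NA` when
a planted count is 0). A single integer seed drives one root random stream;
the generator saves and restores the caller's RNG state.

What the generator does **not** emulate: correlated component–target
profiles (real components share scaffolds and therefore targets), scale-free
degree distributions, curated pathway overlap structure, or
literature-derived edge confidence. Passing recovery tests therefore shows
the chain's statistics behave correctly under the stated sampling model —
not that real association databases satisfy that model.

## Pipeline, determinism and problem sizes

`runPipeline()` validates its config against a closed key schema before any
stage runs (unknown keys are errors, as are missing input paths), executes
the stages load → phenotype-scores → routes → enrichment → compare →
networks with stage-named error reporting, and writes TSV/SIF/GraphML
outputs plus a `manifest.json` (package and R version, seed, config, node
and edge counts) sufficient to reproduce the run. For a fixed seed, repeated
runs are byte-identical.

Test and benchmark problem sizes are deliberately small: random property
graphs of ≤ 25 nodes (100 of them for the walk-vs-oracle check), exhaustive
hypergeometric enumeration up to a 20-gene universe, and 20 generator seeds
for recovery — the full suite runs in well under a minute, and each
individual fixture computation in milliseconds.

## Known limitations

* The fixture's phenotype wiring is uniform by necessity (no per-phenotype
  target lists are published), so per-phenotype results on the fixture are
  identical across phenotypes by construction.
* Route corpora, enrichment universes and network sizes of full
  database-scale analyses (thousands of routes, hundreds of pathways)
  are out of reach of the packaged data; the package reproduces the
  desk-scale quantities exactly and validates the machinery on synthetic
  data at comparable scale.
* The degree-baseline normalization of the walk is one of several defensible
  definitions of a "normalized" propagation score; both raw and normalized
  columns are always reported so users can choose their readout.
* GraphML import/export relies on igraph; SIF stores layers only through the
  id prefix convention.
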