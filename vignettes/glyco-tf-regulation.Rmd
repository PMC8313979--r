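---
title: "Inferring transcription-factor regulation of glycosylation pathways"
author: "GlycoTFNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcription-factor regulation of glycosylation pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GlycoTFNet)
```

# The inference problem

Glycan structures on proteins and lipids are built by the coordinated
action of a few hundred glycogenes — glycosyltransferases, glycosidases,
sulfotransferases and transporters. Which transcription factors (TFs)
drive these glycogenes is largely uncharted. Resources that integrate
ChIP-Seq binding evidence with tumor RNA-Seq (the Cistrome Cancer style of
export) tabulate candidate TF→gene edges, each annotated with

* a **regulatory potential** $RP \in [0, 1]$, a proximity- and
  peak-weighted summary of TF binding near the gene's transcription start
  site, and
* a **Spearman correlation** $\rho \in [-1, 1]$ between TF and target
  expression across tumors of one cancer type.

GlycoTFNet takes such tables and asks three questions, per cancer type:

1. Which TF–glycogene edges are credible positive regulatory
   relationships? (filtering)
2. Which TFs regulate a *disproportionate* share of a curated
   glycosylation pathway? (enrichment)
3. Do TFs act in communities that co-regulate groups of glycogenes, and
   which signaling programs are those communities associated with?
   (network + annotation)

# Model and procedure

## Edge filtering and scoring

An edge is retained when its target lies in the glycogene universe and
$RP \ge 0.5 \wedge \rho \ge 0.4$, both inclusive. The positive $\rho$
cutoff selects activating relationships; repression can be explored by
lowering `rhoMin`, but it is not the default analysis. Each edge also
carries the **binding potential** $BP = RP\cdot\rho$, kept as an edge
attribute for export and layout weighting (Cytoscape layouts use $1-BP$
as a distance), never as a test statistic.

## Pathway enrichment

For one cancer type, with $N$ retained edges in total, a focal TF with
$n$ edges, a pathway containing $K$ of the $N$ edge targets and $a$ of
the focal TF's edges, the one-sided Fisher exact p-value is the
hypergeometric upper tail

$$p = \sum_{j = a}^{\min(K, n)} \frac{\binom{K}{j}\binom{N-K}{n-j}}
      {\binom{N}{n}}.$$

The counting unit is the TF–gene *relationship* (edge). Since
(tf, gene, cancer) is unique, a TF's edges and its unique targets
coincide, but the background margin deliberately uses all retained edges
of the cancer — including edges to glycogenes absent from the pathway
classification, which count as "not in pathway". A
`backgroundClassifiedOnly` switch restricts the margin to classified
genes for sensitivity analysis. Genes belonging to several pathways
(e.g., sialyltransferases, which sit in both the ganglioside and the
sialylation groups) count toward each pathway independently; the tests
are per-pathway marginal tests, not a partition of the edges.

Raw p-values are screened at $p \le 0.05$ (the `significant` flag used
for the per-cancer flow tables) and Benjamini–Hochberg adjusted. The BH
pool is **global across all cancer types** by default, because the
adjusted set is meant to pick the strongest enrichments overall;
`bhScope = "per_cancer"` pools within each cancer instead. Both scopes
are first-class because the choice is genuinely open — reported
refinement counts should be checked under both. The **degree of
regulation** of a (cancer, pathway) pair summarizes its regulatory
pressure as $\sum_{\mathrm{TF}: p_{adj} < 0.05} -\log_{10} p_{adj}$.

Note that BH adjustment is a step-up envelope, not a projection:
re-adjusting already-adjusted values generally inflates them further
(e.g., $(0.1, 0.9) \mapsto (0.2, 0.9) \mapsto (0.4, 0.9)$), so adjusted
p-values must be computed once from raw p-values.

## Communities

Per cancer, the retained edges form a bipartite TF–glycogene graph. The
TF projection connects two TFs with weight equal to their number of
shared targets. Communities are found by Clauset–Newman–Moore greedy
modularity agglomeration, implemented in the package rather than
delegated, so that tie-breaking is fully specified: starting from
singletons, the connected pair with maximal modularity gain is merged
(ties resolved toward the lexicographically smallest community-id pair,
ids being the smallest original vertex index), and the partition with
maximal modularity anywhere along the merge path is returned — not the
cut at the first non-positive gain, which can be a local plateau.
Identical graphs therefore always produce identical partitions, which a
library implementation with unspecified tie handling cannot promise.

Greedy agglomeration is a heuristic: on some graphs no cut of its merge
path attains the global modularity optimum (counterexamples exist with
as few as six vertices, and exhaustive-search comparisons on random
weighted graphs show occasional shortfalls of a few percent in $Q$).
This is accepted; the algorithm choice itself — not global optimality —
is the specified behavior, and planted well-separated structure is
recovered exactly.

Because only the TF projection is clustered, attaching glycogenes to TF
communities needs a rule of our own: each gene joins the community
holding the plurality of its regulating TFs; ties go to the community
with the larger total binding potential toward the gene, then to the
smaller community id. Communities keep 1-based ids in decreasing TF-size
order; singleton communities are retained in output, while "large
community" reporting uses a configurable threshold (default $\ge 5$
TFs).

## Signaling annotation

TF groups (enriched TFs, or the TFs of a community) are tested against
local GMT gene-set collections with the same hypergeometric tail, using
all TFs of the cancer's filtered table as the default universe. A live
Reactome query would use Reactome's own annotated universe, so absolute
p-values will differ between the two routes; only relative behavior is
meaningful here, and no result in this package depends on a specific
Reactome release. Kept sets satisfy strict cutoffs $FDR < 0.1$ and set
size $< 30$. The flow (alluvial) table then links kept signaling sets →
TFs → enriched glyco-pathways, one row per triple, weighted by the TF's
retained edge count into the pathway; TFs without any kept signaling set
are emitted under `"(unassigned)"` so they are not silently dropped.

# The synthetic-data generator

No redistributable instance of the real database export exists, so the
package ships a generator whose defaults emulate the mining setting and
whose ground truth makes recovery measurable.

* **Scale.** 570 TFs, 341 glycogenes, 29 cancer types; about half of the
  TFs are active per cancer (`tfActivity = 0.5`).
* **Background density.** `backgroundEdgeProb = 0.016` per active
  (TF, gene) cell. Together with the activity fraction this reproduces
  both anchors of the real table: roughly 45k raw relationships overall
  and about three retained glycogenes per active TF (range ~1–10).
* **Scores.** True edges draw $RP \sim \mathrm{Beta}(5, 2)$ and $\rho$
  from a scaled $\mathrm{Beta}(32, 8)$ on $[-1, 1]$ (mean 0.6); decoys
  draw $RP \sim \mathrm{Beta}(2, 5)$ and $\rho$ from a scaled, symmetric
  $\mathrm{Beta}(2, 2)$. A background edge is true with probability 0.7.
  Under the default thresholds a true edge survives with probability
  ~0.83 and a decoy with ~0.02, for an overall retained fraction near
  0.6. The $\rho$ concentration is the generator's calibration
  parameter: its mean is fixed, and the concentration is set so that a
  strongly planted pathway (see below) is recovered at the
  FDR-corrected level in at least 95% of replicates — the operating
  characteristic the generator is required to have. RP and $\rho$ are
  drawn independently given edge status; the real joint dependence is
  unknown, and no copula is imposed.
* **Planted pairs.** A planted (TF, pathway, factor $f$) sets the TF's
  edge probability into each pathway gene to
  $\pi(f) = p + (1-p)\,(1 - e^{-(f-1)})$ with $p$ the background
  probability. $f = 1$ reduces *exactly* to the background — permuting
  nothing, a pure null — while $f \ge 5$ saturates the pathway, so the
  planted TF regulates essentially all of its genes. A naive
  relative-risk mechanism $\pi = f\,p$ cannot serve here: with 10-gene
  pathways and ~10³ simultaneous tests, a five-fold risk ratio never
  reaches the raw p-values (~10⁻⁵) that survive FDR correction, at any
  background density, so it cannot be both null-consistent at $f = 1$
  and reliably detectable at $f = 5$. The saturating form is the
  package's own design and is what "an enrichment planted at factor 5"
  means throughout.
* **Planted blocks.** (TF group × gene group) rectangles with an
  elevated within-block edge probability (default 0.8) create TF
  communities with heavy shared-target weights inside and near-zero
  weights between.
* **Determinism.** One seed governs everything; per-cancer streams are
  derived with fixed offsets, so tables are byte-identical across runs
  and the caller's RNG state is restored.

What the generator does **not** emulate: ChIP peaks, read counts or
expression matrices (only the derived (RP, ρ) layer); correlated TF
regulons beyond the planted blocks; HGNC symbol idiosyncrasies; and the
curated classification's exact coverage — pathway memberships are
sampled independently per pathway from a classified pool (61% of genes),
so distinct classified genes number ~120 rather than the pool's 208.
Passing recovery tests therefore demonstrate correctness of the
inference machinery under the assumed error model, not performance on
real Cistrome exports.

# Numerical and interface choices

* Thresholds are inclusive ($\ge$) for RP/ρ filtering; the signaling
  filters are strict ($<$) — both as quoted conventions.
* `hypergeometricTail` delegates to `stats::phyper` (log-space-safe) and
  `benjaminiHochberg` to `stats::p.adjust`; the test suite holds both to
  independent oracles (exhaustive draw enumeration for all $N \le 12$; a
  hand-rolled step-up).
* Duplicate (tf, gene, cancer) rows are a hard ingest error, surfacing
  upstream corruption rather than silently aggregating.
* Symbols are whitespace-trimmed and case-preserved by default with an
  opt-in `uppercase` flag, since real exports vary in case conventions.
* Column names of the export dialect are configurable
  (`cistromeDialect()`); files may be pooled (with a cancer column) or
  per-cancer (cancer code given or inferred from the file name).
* Empty results (no retained edges, no significant TFs, empty
  communities) are returned as empty, schema-stable objects, never
  errors.
* Benchmark problem sizes used by the test suite (50 TFs × 200 genes for
  planted-pair recovery; 24 TFs × 90 genes for block recovery; ≤ 7-node
  graphs for exhaustive modularity comparisons) are chosen so that the
  whole suite runs in minutes on a single core while keeping every
  replicate count at its specified value.

# Limitations

* Community memberships depend on the greedy heuristic's tie-breaking;
  other implementations may split ties differently, and global
  modularity optimality is not guaranteed (see above).
* The signaling annotation is a local-GMT overrepresentation, not a
  Reactome release; counts tied to a specific release are out of scope.
* The pipeline takes RP and ρ as given; it does not model their
  estimation error, nor re-derive them from primary ChIP-Seq/RNA-Seq
  data.
* Cancer-type labels are taken as given; no molecular subtyping is
  performed.
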