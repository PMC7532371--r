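---
title: "Methods: enrichment, crosstalk and MCODE module detection in cmtnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment, crosstalk and MCODE module detection in cmtnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmtnet)
```

## The analysis

`cmtnet` implements the system-level workflow used to study curated disease
gene sets such as the Charcot-Marie-Tooth (CMT) gene set: starting from a
list of literature-curated disease genes, it asks (i) which annotated
biological processes and pathways the set is over-represented in, (ii) how
those enriched processes relate to one another through shared disease genes
("crosstalk"), and (iii) which dense protein-interaction modules the genes
participate in, yielding new candidate genes that co-cluster with known
disease genes.

The pipeline has four computational stages, each usable on its own.

### 1. Curation

Input gene lists are uppercased, trimmed and deduplicated
(`read_gene_list()`), and optionally passed through a user-supplied
alias-to-canonical symbol map (`normalize_symbols()`). Mixed-era symbol
usage (e.g. `GARS` vs `GARS1`) otherwise silently splits a gene into two,
corrupting every downstream count. Two deliberate contracts:

* symbols missing from the alias map are **kept and reported**, never
  dropped — deleting an unrecognized curated gene would silently change the
  size of the query set that every p-value is conditioned on;
* the alias map must be idempotent (no chains `A -> B -> C`), so one
  application reaches the fixed point and normalization is provably
  idempotent.

### 2. Over-representation analysis

For a query of $n$ genes drawn from a universe of $N$ annotated genes, a
term with $K$ members and overlap $k$ is scored by the one-sided Fisher
exact (hypergeometric upper-tail) probability

$$P = \sum_{i \ge k} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

computed by `stats::phyper`. Every term with overlap at least `min_overlap`
(default 1) is tested; Benjamini–Hochberg adjustment (`stats::p.adjust`) is
applied across exactly the tested terms of one namespace, and significance
uses the strict rule `p_bh < 0.05`. Choices worth stating:

* **Sidedness.** One-sided enrichment, the ORA convention; depletion is not
  the question being asked.
* **Background.** Defaults to all genes annotated in the loaded database;
  an explicit background can be supplied in `enrichment_config()`. Query
  genes absent from the background are excluded from $n$ and reported via an
  attribute — counting untestable genes in $n$ inflates significance.
* **BH scope.** Adjustment across tested terms only (the terms with nonzero
  overlap), not the whole database; adjusting across never-tested terms is
  the more liberal reading of some ORA servers, and the tested-rows-only
  default is the conservative, self-consistent one. Separate namespaces
  (e.g. process vs pathway) are adjusted separately.
* **Determinism.** Rows sort by p-value with ties broken by term id.

### 3. Crosstalk network

Significant terms become nodes; the gene set of a node is the set of
*query* genes annotated to it. Two published filters are applied before any
scoring: terms with fewer than 5 query genes are removed (too little
information to support a link), and a pair of terms is connected only when
it shares at least 3 query genes. Each surviving pair $(A, B)$ is scored by
the average of the Jaccard and Overlap coefficients

$$JC = \frac{|A \cap B|}{|A \cup B|}, \qquad
  OC = \frac{|A \cap B|}{\min(|A|, |B|)}, \qquad
  \text{score} = \tfrac{1}{2}(JC + OC),$$

which always satisfy $0 \le JC \le OC \le 1$. Edges are ranked by score; no
further score cutoff is applied, because ranking — not thresholding — is
what the construction prescribes, and any display-time pruning is
presentation, not computation. Terms that survive the 5-gene filter but
have no qualifying partner are kept as isolated nodes and flagged: both the
"qualifying terms" and "connected terms" counts must be derivable from one
graph. Connected components (`graph_components()`) are the computational
analogue of the visually identified "correlative module plus separate
modules" reading of such networks.

### 4. Interactome expansion and MCODE

`expand_seed_network()` maps the seed genes onto an interaction network and
induces the subgraph on the mapped seeds plus all first neighbours,
*including* neighbour–neighbour edges — density-based clustering is
meaningless on a star-shaped expansion. `mcode_clusters()` then runs a
from-scratch implementation of the MCODE molecular-complex detection
algorithm:

1. **Vertex weighting.** Each vertex with degree ≥ `degree_cutoff` (default
   2) is weighted by $k \times \text{density}$ of the highest k-core of its
   closed neighbourhood; others get weight 0.
2. **Cluster growth.** The highest-weight unassigned vertex seeds a
   cluster, which grows breadth-first over unassigned neighbours whose
   weight is at least `seed_weight × (1 − node_score_cutoff)` (default
   cutoff 0.2), to at most `max_depth` (default 100) steps.
3. **Post-processing.** Clusters without a 2-core are discarded; the
   haircut (default on) iteratively removes members with fewer than two
   intra-cluster edges; fluff (default off) may add dense boundary
   neighbours. Scores are `density × n` with loopless density
   $2E/(n(n-1))$; a loop-inclusive variant and pre-haircut scoring are
   available behind flags for parity with some plugin builds, since the
   published description does not pin those details down.

All tie-breaks (seed order, cluster ranking) are lexicographic after score
and size, so the procedure has no randomness at all. The top `top_k`
(default 3) clusters supply the candidate table: their non-seed members,
labelled with every cluster containing them.

A property of MCODE worth knowing when interpreting results: cluster growth
crosses *any* edge whose far endpoint passes the weight threshold. Two
dense modules joined by even a single edge therefore merge into one cluster
whenever their weights are within `node_score_cutoff` of each other (e.g. a
K7 vertex, weight 6, passes the 5.6 threshold of a K8-seeded cluster). This
is faithful to the algorithm — the unit suite asserts it on a two-clique
bridge — but it means that on denser backgrounds the "one cluster = one
complex" reading degrades; see the limitations below.

## The synthetic study

`sim_config()` defines a fully synthetic study with known ground truth so
that every stage is testable without external databases. The defaults are
fixed once, as the package's reference conditions:

| parameter | default | what it emulates |
|---|---|---|
| `n_genes` | 2000 | annotated gene universe |
| `n_seed_genes` | 100 | a curated disease gene set of typical size |
| `n_terms` / `n_true_terms` | 500 / 50 | annotation DB with a truly enriched subset |
| `p_seed_in_true` vs `p_gene_in_term` | 0.5 vs 0.05 | strong seed over-representation against sparse background annotation |
| `term_size_range` | 10–300 | realistic term sizes; out-of-range terms are redrawn |
| `net_n`, `p_background_edge` | 200, 0.02 | Erdős–Rényi interactome backbone (mean degree ≈ 4) |
| `planted_modules` | cliques 8/7/6, 3/2/2 seed members | dense complexes mixing seed and non-seed genes; seed share 25–37%, the range reported for disease-specific PPI clusters |
| `seed_map_prob` | 0.88 | incomplete interactome coverage of curated genes (≈ 88/100 mapped) |

A single integer `rng_seed` drives three *independent derived streams*
(seed set, annotation, interactome), so regenerating one artifact never
perturbs another, and `write_fixture_bundle()` emits files that are
byte-identical across reruns and round-trip exactly through the package's
readers.

What the generator does **not** emulate: scale-free degree distributions,
correlated term hierarchies (GO's DAG), annotation bias toward
well-studied genes, and experimental false-positive edges. Passing the
synthetic benchmarks therefore demonstrates algorithmic correctness and
statistical calibration under idealized structure, not performance on any
particular curated database snapshot.

## Numerical and degenerate-input choices

* Hypergeometric tails come from `phyper(k - 1, K, N - K, n, lower.tail =
  FALSE)`; the unit suite checks them against exhaustive enumeration of all
  $\binom{N}{n}$ subsets for every valid configuration with $N \le 12$
  (tolerance 1e-12).
* `bh_adjust()` rejects p-values outside $(0, 1]$ rather than clamping.
* Empty gene sets are errors for `jaccard()`/`overlap_coef()` (the
  coefficients are undefined), while an empty *edge set* after crosstalk
  filtering is a warning plus an empty graph — a legitimate result.
* A cluster whose haircut removes the original seed vertex is re-rooted at
  its heaviest remaining member; a cluster that loses k-core viability is
  discarded.
* Character ordering uses radix (C-locale) sorting everywhere results are
  ranked or written, so outputs do not depend on the session locale.
* The run manifest contains no wall-clock timestamp: reruns of the same
  configuration must be byte-identical, which a timestamp would break by
  design.

## Problem sizes used by the test suite

The shipped tests run the enrichment operating-characteristics study at the
default conditions (universe 2000, 500 terms, 20 replicates — about half a
minute), exhaustive oracles at $N \le 12$ (hypergeometric) and $\le 7$
vertices (k-core), and the full pipeline end-to-end twice for the
byte-identity check. These sizes were chosen as the smallest at which the
properties under test are non-trivial.

## Known limitations

* The partial CMT gene list shipped in `inst/extdata/` is the recoverable
  subset (~58 symbols) of a ~100-gene curated set; it is a demonstration
  input, and results on it are not comparable to analyses of the full set
  against current GO/KEGG/IID snapshots.
* Enrichment p-values depend on the annotation database and background
  chosen; the package deliberately ships no database.
* MCODE's cluster-growth rule merges bridged dense modules whose weights
  are within the node-score cutoff (see above). On the default synthetic
  interactome this happens for a majority of random seeds: the planted 8-
  and 7-cliques are joined by at least one background edge with probability
  ≈ 0.68. Exact planted-module recovery is therefore asserted on
  bridge-free configurations, and recovery under the default background is
  reported, not guaranteed.
* With `fluff = TRUE` clusters may overlap; candidate tables then contain
  multi-cluster labels (`"Clusters A, B, and C"`), which is the only way a
  standard MCODE run produces them.
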