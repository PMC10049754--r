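---
title: "Annotation engines, synthetic benchmarks and design notes"
author: "celltyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation engines, synthetic benchmarks and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltyper)
```

## The annotation problem

Clustering an scRNA-seq dataset yields groups of cells plus, for each
group, a list of differentially expressed marker genes ranked by a score
such as the log2 fold change. Curated marker databases record which genes
characterise which cell types in which tissues. `celltyper` formalises
"check the markers against the database" as a per-cluster hypothesis test
over candidate cell types, under two complementary models of what a match
means: ranked enrichment (GSEA) and over-representation (Fisher). The
package consumes the DE output table directly; clustering and differential
expression are deliberately upstream concerns.

Both engines assume the marker table is an honest summary of the cluster —
genes are identified in the same key space as the database (Entrez IDs or
symbols, used consistently), scores are finite, and one cluster
corresponds predominantly to one cell type. Clusters that mix cell types
violate the last assumption and are exactly the cases where soft
classification (top-k candidates) is preferable to a single hard label.

## Preranked GSEA engine

Markers are sorted by score descending (ties by gene ID, so rankings are
reproducible; duplicate genes keep their maximum score). For a candidate
set $S$ with $N_H$ members among the $N$ ranked genes, the running sum
after position $i$ is

$$\mathrm{RS}(i) \;=\; \sum_{\substack{j \le i \\ g_j \in S}}
\frac{|r_j|^p}{N_R} \;-\; \sum_{\substack{j \le i \\ g_j \notin S}}
\frac{1}{N - N_H},
\qquad N_R = \sum_{g_j \in S} |r_j|^p ,$$

and the enrichment score is the element of maximal absolute value
(earliest position on ties). The walk necessarily ends at 0, which the
implementation checks to $10^{-9}$.

Significance comes from a gene-label permutation null: `nperm` random
gene sets of the same size, drawn without replacement from the ranked
universe, each scored identically. The p-value uses the plus-one
estimator restricted to null scores of the same sign as the observed ES,
$p = (1 + \#\{|ES_0| \ge |ES|\}) / (1 + \#\{\text{same sign}\})$, so it
can never be exactly zero and is floored at $1/(\mathrm{nperm}+1)$. The
normalized score divides ES by the mean magnitude of same-sign null
scores; when no null shares the sign, NES is reported as missing.

### The ranked universe

The walk is computed over the union of the cluster's markers and the
database's genes: genes the database knows but the DE table did not
report are appended at score 0 (sorted by ID among themselves, between
positive and negative scores). Two reasons. First, it makes the GSEA and
Fisher branches use the same background, so their rankings are
comparable. Second, it keeps the statistic defined in the boundary case
where every reported marker belongs to one candidate set — with the bare
marker list there would be no non-member genes to walk over, and the
strongest possible annotation evidence would be untestable. Zero-score
genes carry zero weight at the default exponent, so they only lengthen
the miss segments of the walk; the permutation null is drawn from the
same augmented universe, so observed and null scores remain exchangeable
under the null.

### Tunables

| parameter | default | meaning |
|---|---|---|
| `weight_exponent` | 1 | exponent $p$ on the absolute score; 0 gives the unweighted KS statistic |
| `nperm` | 1000 | permutation count; resolves p down to ~0.001 |
| `seed` | 1 | controls the permutation draw; nulls for different set sizes use offset seeds and are cached per size |
| `score_type` | `"pos"` | DE marker lists are typically up-regulated markers, so negatively enriched candidates rank after all non-negative ones; `"std"` keeps fully signed ordering |
| `min_set_size` | 2 | singleton sets trivially attain the maximal ES and are excluded |
| `max_set_size` | 500 | guards against catch-all sets dominating the universe |

## Fisher engine

For each candidate cell type, the 2×2 table cross-classifies a background
universe by marker membership and set membership, and the p-value is the
exact hypergeometric upper tail (one-sided: annotation only asks about
over-representation). The tail is accumulated from log-space pmf terms,
so universes up to ~1e5 genes evaluate without underflow.

The universe is the union of the (tissue-filtered) database genes and the
cluster's markers. This is self-contained — no genome annotation needed —
stable across runs, and conservative: adding unrelated genes to the
universe could only make overlaps look more surprising.

One test per (cluster, cell type) pair is the chosen granularity: a
candidate label needs exactly one p-value for the downstream ranking, and
the contingency-table logic of "how many of the cluster's markers are
known markers of T?" maps directly onto a single 2×2 table. A per-marker
test family would need an aggregation rule that has no natural
definition here and is not implemented.

Expression scores enter as the secondary ranking key: candidates sort by
adjusted p, then by the mean score of the overlapping markers, then by
overlap size, then by name. Identical sets (common in databases where
two subtype entries share a panel) therefore tie deterministically, and
a candidate supported by strongly up-regulated markers outranks one
supported by marginal ones at the same p.

## Multiple testing and classification

Benjamini–Hochberg adjustment is applied within each cluster, across the
candidate cell types tested for that cluster, in both engines. Applying
it in both (rather than only in the Fisher branch) keeps the two sets of
results comparable and the raw p-values are reported alongside. The hard
label is the top-ranked candidate; soft classification truncates the
ranking at k (default 5, the depth at which candidate lists stay
reviewable by eye). The hard label is by construction the first soft
label, so soft accuracy can never fall below hard accuracy.

Clusters for which no candidate survives the size bounds are reported
`unassigned` rather than silently dropped, and count as incorrect in the
accuracy metric.

## Plot tables

Dot plots (clusters × top-k candidates) and per-cluster bar plots (up to
10 candidates) encode significance as $-\log_{10}(\text{adjusted } p)$
clipped to $[0, 10]$. Only the ordering is meaningful; the clip keeps
permutation-p floors from dominating the scale. The tables are pure
functions of the report and are the tested surface; rendering is an
optional `ggplot2` layer.

## Synthetic benchmark

`synthetic_scenario()` describes a ground-truthed world: a database of
`n_cell_types` sets with `markers_per_type` genes each, adjacent types
sharing `floor(marker_overlap_frac × markers_per_type)` genes (emulating
related subtypes such as T-cell subsets, the hard case for annotation),
and per-cluster reported marker tables in which a fraction `noise_frac`
of rows are decoy genes belonging to no set. True markers draw scores
uniformly on [1, 3] and decoys on [0.1, 0.8]: genuine markers
stochastically dominate, as log-fold-changes of real markers dominate
those of noise genes, while still overlapping enough that ranking is not
trivial. Gene tokens are assigned to sets in seed-shuffled order so that
set membership does not correlate with identifier order.

The defaults — 8 cell types, 20 markers per type, 20 reported markers of
which 20% are noise, 200 cells per cluster (1600 cells total) — emulate a
PBMC-like panel at a size where a full Monte Carlo sweep runs in seconds.
The simulator produces marker *tables*, not expression matrices: the
annotation engines only ever see DE output, so the ranked marker list is
the sufficient statistic, and `cells_per_cluster` preserves the per-cell
weighting of the accuracy metric (a cluster's cells are all correct or
all incorrect together).

What passing synthetic benchmarks does **not** show: robustness to
clusters that mix cell types, to systematic DE artefacts (batch effects,
ambient RNA), to database errors, or to ID-mapping losses. Those failure
modes live upstream of the statistic being tested here.

Accuracy is $\sum_c n_c \mathbf{1}\{\text{correct}(c)\} / \sum_c n_c$
with $n_c$ the cluster's cell count; hard correctness compares the hard
label with the truth, soft correctness asks whether the truth appears in
the top-k.

## Numerical and degenerate-input choices

- **Peak selection tolerance.** Exact analytic ties in $|\mathrm{RS}|$
  (e.g. $-0.5$ then $+0.5$ on a short list) can differ by one ulp after
  accumulation, so the earliest-maximum rule tolerates $10^{-9}$ — far
  below the smallest genuine gap between distinct deviations, which is at
  least $1/(N(N-N_H))$.
- **All-zero member scores** make the weighted hit mass degenerate; the
  set falls back to the unweighted statistic ($p = 0$) rather than
  erroring.
- **Duplicate genes** within a cluster keep their maximum score — DE
  tables occasionally repeat genes across contrasts, and the strongest
  signal is the informative one.
- **Ties everywhere** break by name (gene ID, cell type) so that repeated
  runs, and runs on the same data across machines, produce byte-identical
  outputs. All randomness flows from explicit seeds.
- **Unmapped symbols and unparseable scores** are dropped with a warning,
  never silently: real DE output contains both, and refusing the whole
  table would be worse than annotating the mappable part.

## Problem sizes used by the test suite

The suite verifies the hypergeometric tail against exhaustive enumeration
for every 2×2 table with universe ≤ 25; the enrichment score against a
naive double-loop oracle on 500 random instances with N ≤ 50; BH against
a direct transcription of the step-up formula on 1000 random vectors;
permutation-p calibration on 500 null replicates at `nperm = 1000`;
clean-signal recovery over 20 seeds of the default scenario; and the
noise sweep at 10 seeds per level with 40% marker overlap — sizes chosen
so the full suite completes in about a minute while keeping Monte Carlo
margins wide.

## Known limitations

- The permutation null is the standard gene-label null; it ignores
  inter-gene correlation within marker panels, as preranked GSEA
  implementations generally do.
- Annotation quality is bounded by the database: cell types absent from
  the (tissue-filtered) database cannot be proposed, and tissue keywords
  that match nothing raise an error rather than falling back to the whole
  database.
- The per-cluster BH family is small (one test per candidate cell type);
  FDR control is within cluster, not experiment-wide.
- Scores are taken as given; the engines do not model the uncertainty of
  the upstream DE statistics.
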