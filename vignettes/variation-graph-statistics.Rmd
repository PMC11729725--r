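---
title: "Measuring pangenome variation graphs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pangenome variation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgstats)
library(data.table)
```

## The graph model

A GFAv1 variation graph is bidirected: every segment (node) has two ends, a
link attaches an oriented end of one node to an oriented end of another, and
a link is the *same edge* as its reverse complement (swap endpoints, flip
both orientations). `vgstats` therefore stores each edge once, in a
canonical form: of the two equivalent tuples, the lexicographically smaller
under (id ascending, then `+` before `-`). Duplicate L records and mirrored
records collapse to one edge; `edge_count` counts canonical edges.

One consequence worth knowing: the split of non-inverted links into
"forward-forward" and "reverse-reverse" (`links_ff_count`,
`links_rr_count`) depends on which representative is canonical, and hence on
the id order. Their *sum* and the inverted-link count are intrinsic to the
graph; the split is only comparable between graphs whose ids are ordered the
same way (e.g. both relabeled with `node2int()`).

Paths are ordered lists of oriented node traversals and represent the input
haplotypes. Sample identity is derived from the PanSN convention
`sample#haplotype#contig`: everything before the first `#` is the sample;
names without `#` are their own sample. This distinction matters because a
human pangenome graph typically has many paths (contigs) per haplotype and
two haplotypes per sample: node *depth* counts steps with multiplicity,
while node *similarity* (occupancy) counts distinct samples. A
`by_haplotype` switch reinterprets `sample#haplotype` as the unit where
haplotype-level resolution is wanted.

All coordinates are 0-based and half-open. Links with overlaps other than
`*`/`0M` are accepted with a warning, and every bp statistic treats the
graph as blunt-ended: subtracting CIGAR overlaps from lengths is not
attempted, matching the output of the common all-vs-all aligner pipelines
which emit `0M`. Segments with `*` sequence are supported through their
`LN:i:` tag, since no statistic inspects base identity — only lengths.

## The metric catalog

`graph_stats_report()` returns exactly 108 named metrics in a frozen order
(a golden-file test guards names and order; adding a metric is a breaking
change). The groups:

| group | metrics | notes |
|---|---|---|
| size & composition | 12 | counts, bp totals, compression ratio, density, components |
| orientation & loops | 6 | self-loops, ff/rr/inverted link counts |
| node length | 7 | five-number summary + N50/N90 |
| degree | 15 | total/in/out × five summaries |
| depth | 6 | five summaries + zero-depth count |
| node similarity | 5 | five summaries over visited nodes |
| pan-classification | 9 | private/shell/core counts and bp, softcore |
| jumps | 8 | totals, summaries, threshold exceedances, sortedness |
| path distributions | 35 | 7 per-path features × five summaries |
| edge depth | 5 | five summaries |

Numerical conventions, chosen once and applied everywhere:

* **Standard deviations** use the population (n) denominator: the metrics
  describe the whole graph, not a sample from it.
* **Medians** of an even count average the two central values.
* **graph_density** uses the undirected simple-graph denominator
  `N(N-1)/2`, with self-loops excluded from the numerator, so values are
  bounded and comparable across graphs.
* **Zero-depth nodes** (present as segments but on no path) are included in
  size/length/degree groups but excluded from similarity summaries and the
  pan-classes — they belong to no sample. The partition invariant is
  `private + shell + core + zero_depth == node_count`.
* **Degenerate inputs** degrade to `NA`, never to errors: an empty graph
  still yields a 108-row report with `NA` where a summary is undefined
  (written as literal `NA` in TSV and `null` in JSON, keeping the shape
  stable for downstream parsing). An empty length vector makes `nX()`
  return 0.

### Jumps and id sortedness

The jump of consecutive steps is the raw absolute id difference
`|id(b) - id(a)|` (not `|Δ|-1`). Jump statistics are only meaningful on a
numeric and reasonably sorted id space — typically the product of
path-guided 1D layout sorting — so two guards are built in: non-numeric ids
produce `NA` jump metrics with a pointer to `node2int()` (this includes the
five per-path jump-total summaries, which read the same ids), and
`id_sortedness` (fraction of adjacent pairs with increasing ids) is
reported as a diagnostic of whether the other jump metrics are worth
reading. The exceedance threshold defaults to 1000 ids — large enough to
ignore local bubble structure, small enough to flag long-range links —
and is configurable everywhere it is used.

`node2int()` assigns new ids 1..N in order of first appearance as S
records. With that rule, relabeling and then normalizing restores the
original report exactly (including the ff/rr split discussed above)
whenever the original ids were already 1..N in record order, which is how
the relabeling-invariance property is tested.

## Pangenome partition and growth

Node occupancy `s_v` is the number of distinct samples traversing node `v`.
Classes: `private` (`s_v = 1`), `core` (`s_v = S`), `shell` (everything
between), `absent` (`s_v = 0`). With `S = 1` a visited node is both
private and core by the formulas; the package reports `core`, since
"core" is defined relative to all samples present. The *softcore* count
(`s_v >= ceiling(0.95 S)` by default) is reported as a flag and a count,
deliberately not as a fifth class, so that the partition invariant above
holds exactly; 0.95 is this package's default, adjustable via
`softcore_frac`.

Two growth-curve estimators are provided because both conventions are
common in pangenomics:

* `growth_exact()` evaluates the expectation over all `k`-subsets of
  samples in closed form with hypergeometric terms
  (`1 - C(S-s_v, k)/C(S, k)` for the pan curve, `C(s_v, k)/C(S, k)` for
  the core curve), computed via `lchoose` so that out-of-range binomials
  are exact zeros and large `S` does not overflow.
* `growth_permutation()` shuffles sample order with a seeded generator and
  averages cumulative-union/running-intersection curves over replicates —
  the estimator that generalizes to quantiles and to order-dependent
  summaries. With the seed recorded, output is bit-reproducible.

The exact curve is tested against explicit subset enumeration (`S <= 6`),
and the permutation curve against the exact one at 2000 replicates. Both
report node and bp units; bp is recommended for cross-graph comparisons
since node counts are construction-dependent.

Sample similarity is the length-weighted Jaccard index over distinct node
sets — the bp of shared nodes over the bp of the union — which feeds
standard clustering/ordination directly and is invariant under relabeling.

## Sliding windows

`sliding_windows()` profiles a statistic (`depth`, `similarity`, `degree`,
`node_length`, `private_frac`, `jump`) along each path, in `steps` or `bp`
mode. In bp mode every base inherits its step's node statistic. Window
values are plain means; `private_frac` is the fraction of steps/bases on
occupancy-1 nodes. Two deliberate choices:

* Trailing partial windows are dropped by default so all values average the
  same denominator; `keep_tail = TRUE` appends the final short window
  flagged in a `partial` column instead.
* Jumps are anchored at the left step of each pair; the final step of a
  path carries no jump and is excluded from jump-window means.

Reverse-orientation steps contribute their statistic exactly like forward
steps; orientation enters only through the per-path inverted-step fraction,
which is not a window statistic. With tiling windows (`step == size`) in bp
mode, the window means aggregate back to the whole-path mean over the
covered prefix, which is the property tested.

## The simulator and what it does (not) emulate

`simulate_graph()` builds a bubble chain: backbone nodes alternate with `B`
bubbles of four types. A `snp` contributes two alternative 1-bp nodes; an
`insertion` one optional node that allele carriers traverse; a `deletion`
one node that carriers *skip* (the mirror of the insertion, so backbone
occupancy stays at `S` and truth bookkeeping is exact even for adjacent
bubbles); an `inversion` one node all samples traverse, carriers with `-`
orientation. Each of the `S` samples (one path per sample; multi-haplotype
cases are constructed in tests by PanSN-naming two paths with a shared
prefix) picks each bubble's alternative allele independently with the
bubble frequency `f` — fixed, or drawn per bubble from a Beta when allele
frequency heterogeneity is wanted.

Defaults: backbone and structural-variant node lengths are drawn uniformly
from 5–10 bp and `f = 0.5`, giving small, dense graphs in which every class
(core, shell, private, absent) is exercised; tests that need particular
regimes (e.g. forced-divergent SNPs, `S` up to 8, hundreds of bubbles) set
the config explicitly. Node ids are emitted 1..N along the chain, so
simulated graphs have a sorted id space and a small jump ceiling by
construction; `shuffle_ids = TRUE` permutes the labels (keeping record
order) to create high-jump graphs and to exercise relabeling.

The truth sheet records, per node, the realized sample occupancy, class and
role, plus expected node/edge/class counts and per-sample path lengths —
recorded during construction, before any parsing, so recovery tests compare
two independent routes. Everything is driven by one seeded generator:
identical configs give byte-identical GFA text and truth.

What the simulator does *not* emulate: realistic sequence content or
mutation spectra, nested/overlapping bubbles, collapsed repeats (depth > 1
per path), translocations, or the artifacts of real construction pipelines.
Passing tests therefore demonstrate correctness of the statistics on graphs
with known structure, not robustness to every topology a PGGB or
Minigraph-Cactus run can produce; the parser-level validation and the
degenerate fixtures (self-loops, isolated nodes, inversions, empty graphs)
cover the sharp edges we know about.

## Problem sizes and performance

All profiles are computed in single passes over links and steps with
vectorized table operations, so time grows close to linearly in
(nodes + edges + total steps). The test suite exercises the full pipeline
on graphs up to ~120k nodes / ~170k edges / ~400k steps (a 50 000-bubble,
4-sample simulation), where parse + full 108-metric report completes in
seconds; the scaling check compares that against a ~12k-node graph from the
same config family and asserts a sub-20× ratio for 10× the nodes.
Convergence checks use 2000 permutation replicates on a ~1000-node graph.

## Known limitations

* Overlap-aware length accounting (non-`0M` CIGARs) is not implemented;
  such graphs are measured as blunt-ended.
* GFAv2, containment (C) records, and sequence-content statistics are out
  of scope.
* The ff/rr link split is id-order dependent (see above).
* `jump` thresholds and the softcore fraction are conventions, not
  estimates; cross-study comparisons should pin them explicitly.
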