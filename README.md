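# vgstats — statistics for GFAv1 pangenome variation graphs

Pangenome variation graphs condense the genomes of many samples into a single
bidirected sequence graph: nodes carry DNA segments, edges connect oriented
node ends, and each input haplotype is embedded as a *path* of oriented node
traversals. Graph shape depends strongly on the construction pipeline and its
parameters, so the first step after building a graph is usually to measure
it. `vgstats` is an R toolkit for exactly that step: it parses GFAv1 graphs
(S/L/P records, plus W walks) and computes analysis-ready tables for graph
evaluation, pangenome structure and sample-level comparison.

What it computes:

* **108-metric catalog** (`graph_stats_report()`): a frozen, ordered set of
  graph-level metrics — size and composition (node/edge/path/sample counts,
  compression ratio = total path bp / graph bp, density, components),
  orientation and loop counts, node-length distribution with N50/N90, degree,
  depth (path coverage per node), node similarity (distinct samples per
  node), core/shell/private partition, jump statistics, per-path
  distributions, and edge traversal depth.
* **Per-path statistics** (`path_stats_table()`): one row per haplotype path
  (length, steps, inversions, jumps, mean depth/degree/similarity, private
  and core bp).
* **Pangenome analytics**: node classification by sample occupancy
  (`classify_nodes()`), exact hypergeometric and permutation genome-growth
  curves (`growth_exact()`, `growth_permutation()`), per-path occupancy
  profiles (`path_pangenome_profile()`), and length-weighted Jaccard sample
  similarity (`sample_similarity_matrix()`).
* **Sliding windows** (`sliding_windows()`): node-level statistics in windows
  along each path, on step or bp coordinates, as BED-like tables.
* **Plumbing**: numeric node-id relabeling (`node2int()`; jump statistics
  require numeric, ideally sorted, id spaces), a GFA writer, and a seeded
  synthetic-graph simulator with per-node ground truth (`simulate_graph()`).

The core quantities, in the field's usual notation: for a node $v$ with
length $\ell_v$ present in $s_v$ of $S$ samples, the node is *private* when
$s_v = 1$, *core* when $s_v = S$, *shell* otherwise. The expected pangenome
growth over random $k$-subsets of samples is computed in closed form,

$$\mathrm{pan}(k) = \sum_v \left(1 - \binom{S-s_v}{k}\Big/\binom{S}{k}\right),
\qquad
\mathrm{core}(k) = \sum_v \binom{s_v}{k}\Big/\binom{S}{k},$$

with bp-weighted variants multiplying each term by $\ell_v$. The *jump* of
two consecutive path steps is $|\,\mathrm{id}(b)-\mathrm{id}(a)\,|$; the
similarity of samples $i,j$ is the length-weighted Jaccard index of their
node sets.

## Worked example

Using the bundled toy graph (4 nodes, two paths `x` and `y` through a double
bubble; `inst/extdata/toy1.gfa`):

```r
library(vgstats)
g <- parse_gfa(system.file("extdata", "toy1.gfa", package = "vgstats"))
g
#> variation_graph: 4 segments, 4 links, 2 paths, 2 samples; 8 bp; numeric ids

rep <- graph_stats_report(g)
rep[metric %in% c("node_count", "compression_ratio", "core_node_count",
                  "private_bp", "jump_total", "id_sortedness")]
#>               metric value
#>               <char> <num>
#> 1:        node_count  4.00
#> 2: compression_ratio  1.75
#> 3:        private_bp  2.00
#> 4:   core_node_count  2.00
#> 5:        jump_total  6.00
#> 6:     id_sortedness  1.00

growth_exact(g)
#>        k pan_nodes pan_bp core_nodes core_bp
#>    <int>     <num>  <num>      <num>   <num>
#> 1:     1         3      7          3       7
#> 2:     2         4      8          2       6

sample_similarity_matrix(g)
#>      x    y
#> x 1.00 0.75
#> y 0.75 1.00
```

Reading: the 14 bp of path sequence compress into 8 bp of graph
(`compression_ratio` 1.75); two nodes are core (on both samples, 6 bp) and
two are private (1 bp each); a single random sample already shows 7 of the
8 pangenome bp (`pan_bp(1) = 7`); the two samples share 75% of their
length-weighted node content.

The same analyses are available from the shell via the bundled script
(installed at `exec/vgstats`):

```sh
vgstats stats -g graph.gfa -o stats.tsv        # 108-row metric TSV
vgstats stats a.gfa b.gfa -o batch.tsv         # one column per graph
vgstats growth -g graph.gfa --mode exact
vgstats core -g graph.gfa --summary classes.tsv
vgstats window -g graph.gfa --statistic similarity --size 1000 --mode bp
vgstats node2int -g strings.gfa -o ints.gfa --map map.tsv
vgstats simulate --samples 8 --bubbles 200 --seed 1 --prefix sim
```

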