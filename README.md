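# poaflow

Partial order alignment (POA) graphs rendered as Sankey diagrams, as a
batch R library and command-line tool.

A multiple sequence alignment (MSA) is usually shown as a matrix of rows.
The POA view of the same alignment is a directed acyclic graph: each
alignment column is a cluster of nodes, identical residues within a column
are merged into one node, and every sequence traces a path through the
graph. The shared nodes of those paths are the aligned identical residues,
so conservation and divergence become visible as merging and splitting
flows. `poaflow` draws this graph as a column-constrained Sankey diagram in
which the height of each node and the thickness of each arc are
proportional to the flow — here, the number of member sequences — alongside
a column-synchronized alignment-matrix panel and an optional phylogenetic
tree panel.

For whom: anyone inspecting an existing MSA — protein families,
overlapping long reads, alternative loci — who wants a structural view
rather than rows of letters. The package does not align sequences; it
visualizes alignments computed elsewhere.

## What it computes

Given an alignment `A` with sequences `s = 0..n-1`:

- **POA graph.** One node per (column `c`, residue `x`) with member set
  `M(c,x) = { s : A[s,c] = x }`; one edge per ordered pair of consecutive
  non-gap positions of a sequence, merged over sequences. Gap stretches
  yield "long" edges spanning several columns. Flow is conserved: every
  node's member count equals the sum of its incoming edge counts plus the
  sequences starting there.
- **Simplified graph.** Within each column, nodes whose residues share a
  physicochemical class (electrically charged `{D,E,K,R,H}`, polar
  uncharged `{S,T,N,Q,Y}`, hydrophobic `{A,V,L,I,M,F,W}`, special
  `{C,G,P}`, everything else `other`) are merged — useful for divergent
  protein alignments. The classification is fully user-replaceable.
- **Consensus path.** The source-to-sink path maximizing cumulative
  per-edge sequence support (dynamic programming over the column-ordered
  DAG, deterministic tie-breaks), e.g. the error-corrected read through a
  pile of overlapping reads.
- **Layout and rendering.** Uniform column spacing, flow-proportional
  geometry, barycenter vertical ordering, selection-aware nested sublinks,
  and deterministic SVG output with Sankey, matrix and tree panels whose
  coordinates agree exactly.

Input formats: FASTA (aligned), Clustal, MSF, Phylip (relaxed or strict,
sequential or interleaved), Stockholm; trees in Newick.

## Worked example

```r
library(poaflow)

aln <- generate_msa_fixture(8, 40, "protein",
                            substitution_rate = 0.35, gap_rate = 0.1,
                            seed = 42)
g <- build_poa(aln)
g
#> <poa_graph> 40 columns, 8 sequences, 144 nodes, 209 edges (protein)
```

144 nodes over 40 columns means 3.6 residue variants per column on
average — a fairly divergent family. Simplifying by physicochemical class
collapses a third of them:

```r
simplify_poa(g)
#> <poa_graph> 40 columns, 8 sequences, 98 nodes, 160 edges (protein)

cons <- consensus_path(g)
head(cons$path, 5); cons$weight
#> [1] "0/T" "1/F" "2/A" "3/L" "4/E"
#> [1] 120
```

The consensus path carries total support 120: summed over its edges, 120
sequence transitions follow it (the theoretical maximum would be all 8
sequences along every one of its 38 edges plus endpoints). Node ids are
`column/symbol` with 0-based columns.

```r
lay <- compute_layout(g, layout_config(canvas_width = 1200,
                                       canvas_height = 500))
sel <- parse_selection(c("seq:s2", "node:0/T"), g)
sel
#> <selection_state> 5/8 selected: 0, 1, 2, 3, 4

svg <- render_svg(g, lay, aln,
                  tree = generate_tree_fixture(aln$ids, seed = 43),
                  selection = sel, consensus = cons$path)
writeLines(svg, "family.svg")
```

`parse_selection` replays the interactive toggle actions: `seq:s2` toggles
one sequence, `node:0/T` toggles every sequence passing through node `T`
in the first column (here adding four more). Selected sequences are drawn
as highlighted sublinks nested inside each ribbon, with matching
highlights on matrix row labels and tree subtrees.

The same pipeline from a shell:

```sh
inst/cli/poaflow render family.fasta --tree family.nwk \
    --range 10:30 --select seq:s2 --highlight-consensus -o family.svg
inst/cli/poaflow inspect family.fasta
#> {"n_sequences":8,"n_columns":40,"alphabet":"protein","n_nodes":144,
#>  "n_edges":209,"nodes_per_column":{"min":2,"max":6,"mean":3.6},
#>  "consensus":{"length":39,"weight":120}}
```

`--range` is 1-based inclusive; exit codes are 0 (success), 2 (input
error), 1 (internal error).

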