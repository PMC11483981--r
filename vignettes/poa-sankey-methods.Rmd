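---
title: "Visualizing partial order alignments as Sankey diagrams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing partial order alignments as Sankey diagrams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poaflow)
```

## The model

A multiple sequence alignment (MSA) asserts, column by column, which
residues of its sequences are homologous. The partial order alignment
(POA) view re-encodes the same information as a directed acyclic graph:

- the node set is partitioned into clusters, one per alignment column;
- within a column, all sequences showing the same residue share a single
  node, whose *members* are those sequences;
- a directed edge connects each pair of consecutive non-gap positions of
  a sequence; edges between the same node pair are merged and their
  member sets unioned.

Each sequence is then a path through the graph, and the graph is exactly
equivalent to the MSA: `reconstruct_alignment(build_poa(A))` recovers `A`
symbol for symbol, and the test suite holds this as a hard invariant over
hundreds of random alignments. Where a sequence has a run of gaps, its
edge spans several columns (a *long link*); such an edge certifies that
every strictly intermediate column holds gaps for each of its members.

Flow is conserved by construction: a node's member count equals the sum
of its incoming edge counts plus the number of sequences whose path
starts there (symmetrically for outgoing edges and path ends). This
conservation law is what makes the Sankey rendering faithful — node
heights and ribbon thicknesses are both `count × flow_unit`, so merging
and splitting flows tile each node side with no gap and no overlap.

Sequences are unweighted; "flow" always means the number of member
sequences. Node identifiers are `column/symbol` strings with 0-based
columns, chosen because they are stable across runs and need no hidden
counters (all rendered column labels are 1-based, converted once at the
presentation boundary).

## Input handling

Five alignment formats are accepted (FASTA, Clustal, MSF, Phylip,
Stockholm), detected by their first non-blank line; detection never
guesses between formats. Symbols are upper-cased and `.` gaps normalized
to `-` on read, since the formats disagree on both conventions.
Ambiguity codes (`N`, `X`, `B`, `Z`, ...) are legal symbols and form their
own nodes. Phylip is tried in its relaxed, whitespace-delimited dialect
first, falling back to the strict 10-character-name dialect only when the
relaxed parse does not match the header dimensions — relaxed dominates
modern usage. The alphabet is inferred as nucleotide when at least 95% of
non-gap symbols lie in `{A,C,G,T,U,N}`, and can always be overridden.

Trees come as Newick; a tree is only ever used when its leaf label set
*equals* the alignment id set. A tree whose leaves are a strict subset
could plausibly be auto-pruned or auto-extended, but either guess can
silently mislabel rows, so any mismatch is rejected with the offending
ids named on both sides.

## Simplification by residue class

Divergent protein alignments share few identical residues per column, so
the full POA graph fragments into many thin nodes. Merging nodes whose
residues share physicochemical behavior recovers readability. The default
partition of the 20 standard amino acids:

| group                | residues        |
|----------------------|-----------------|
| electrically charged | D, E, K, R, H   |
| polar uncharged      | S, T, N, Q, Y   |
| hydrophobic          | A, V, L, I, M, F, W |
| special              | C, G, P         |

Unmapped symbols fall into `other`, so a column never holds more than
five group nodes. The class memberships follow the common side-chain
classification; because conventions differ at the margins (H, G, C are
argued into different classes by different authors), the grouping is data,
not code — any named list of symbol sets can replace it, including a
purine/pyrimidine partition for nucleotide input. Simplification is
idempotent (group labels map to themselves) and conserves per-column
membership exactly.

## Consensus path

The consensus is defined here as the source-to-sink path maximizing
cumulative sequence support, with a virtual start (end) connected to every
node where at least one sequence starts (ends), weighted by the number of
such sequences, and each edge contributing its member count. Support is
counted **per edge**: a path is rewarded for each sequence transition it
follows, which mirrors common POA consensus practice (per-node counting is
the other defensible choice; the per-edge decision is deliberate and
documented here).

The maximum is computed by a reverse dynamic-programming sweep in column
order followed by a greedy forward walk. Deciding ties during the forward
walk makes the tie-break apply at the *earliest divergence* between
equally heavy paths: prefer the node with more members, then the
lexicographically smaller symbol, then the smaller column. When stopping
at a valid sequence end ties with continuing, the walk continues — longer
paths win ties. These rules make the result a deterministic function of
the graph. The dynamic program is validated against exhaustive
enumeration of all source-to-sink paths on thousands of small graphs
(up to 4 sequences × 6 columns over `{A, C, -}`, including a fully
enumerated census of the smallest shapes).

## Selection semantics

Highlighting operates on a set of selected sequence indices mutated by
three toggle actions: one sequence, all descendant leaves of a tree node,
or all members of a POA node. Single-sequence toggles flip membership.
Group toggles use an *add-unless-fully-selected* rule: if the target set
is entirely selected it is removed, otherwise it is added in full. For
partially overlapping sets the alternative (remove the overlap) would
make a double click non-idempotent from clean states; the chosen rule
keeps both branches reachable and every toggle an involution whenever the
target set starts fully present or fully absent. This is a design choice
of this package, not an inferred behavior of any other tool. Selections
serialize to one-line expressions (`seq:ID`, `clade:LABEL`,
`node:COL/SYMBOL`) so batch runs can replay an interactive session.

## Layout

Columns of the displayed range are placed left to right at uniform
spacing; a range view clips edges with one endpoint outside the range
into horizontal stubs at the canvas boundary, preserving side tiling so
partial views still conserve flow visually.

**Flow unit.** Unless fixed by the user, the canvas-height-per-sequence
unit is auto-scaled so the fullest column exactly fits the canvas.

**Exactness.** Two quantities are deliberately quantized to multiples of
1/1024 canvas units: the column spacing and the auto-scaled flow unit.
Dyadic values make the uniform-spacing invariant (`max gap − min gap = 0`)
and the conservation invariants (sublink thicknesses summing to their
parent, link thicknesses tiling node sides) hold *exactly* in floating
point rather than to rounding error, which in turn lets the test suite
assert them with `identical()`. The visual cost is below one part in a
thousand of a pixel-scale unit.

**Vertical order.** Within a column, nodes start sorted by descending
member count (ties by symbol), then two barycenter passes run: one left
to right ordering each column by the mean y-center of the already-placed
predecessors, one right to left by successors. Nodes without neighbors
keep their position; sorting is stable. Barycenter sweeps are the
standard cheap heuristic of layered graph drawing; no crossing-minimizing
optimization is attempted (an ILP or force simulation would break the
run-time guarantees on large graphs for modest visual gain). Manual
`y_overrides` — the batch equivalent of dragging a node — are applied
last and are excluded from the proportionality invariants.

**Link shapes.** POA graphs are DAGs, so the layout only ever emits
forward ribbons (cubic ribbons from the right side of the source to the
left side of the target, with control points at the horizontal midpoint,
making each boundary curve monotone in x) and boundary stubs. The
geometry engine additionally supports *feedback arcs* (target left of
source, routed below the occupied canvas band) and *reversing joins*
(connecting two left or two right sides, looping off that side), which
cyclic or bidirected graphs — e.g. pangenome variation graphs — require.
These shapes are exercised by engine-level tests only.

**Drawing order.** Links draw longest column span first (underneath),
then thicker before thinner, stably — long background links never occlude
the short local structure.

## Rendering

Output is a single SVG 1.1 document (optionally wrapped unchanged in a
static HTML page) with up to three panels:

- the Sankey panel: one `rect` per node, one `path` per link sublink;
- the matrix panel below it, whose cells reuse the *same* column
  x-coordinates and widths as the Sankey columns;
- an optional rectangular cladogram at the left, whose leaf order defines
  the matrix row order and whose leaf y-centers equal the matrix row
  y-centers exactly.

The cladogram ignores branch lengths: row alignment with the matrix is
the contract, and uniform depth steps keep deep trees legible. Children
are ladderized deterministically (smaller clades first, ties by smallest
descendant label). An edge is highlighted exactly when every leaf below
it is selected.

Determinism is treated as a correctness property: fixed iteration
orders, a fixed-precision number formatter, a built-in text-metrics table
instead of OS font queries, and no timestamps make identical inputs give
byte-identical documents. Hover bubbles of interactive viewers are
replaced by embedded `<title>` descriptions (column, symbol, member ids),
which SVG viewers show as tooltips. One color scheme drives both the
Sankey nodes and matrix cells (4+N nucleotide palette, Clustal-like
protein palette, or one color per residue group); every scheme resolves
unknown symbols to a fallback color rather than erroring. Unselected
flows dim to a configurable opacity while a selection is active;
selected sublinks and the optional consensus chain use the scheme's
highlight color.

## Synthetic data

The fixture generator draws a random ancestral row and derives each
sequence by independent per-column substitution (default rate 0.2) and
gap insertion (default rate 0.1) — a star phylogeny, chosen as a neutral
default for a format-and-geometry tool: moderate column diversity,
realistic gap density, no structure that would favor any particular
layout. All-gap rows and columns are repaired deterministically so every
output satisfies the alignment invariants. What it does *not* emulate:
indel blocks (gaps are i.i.d., real indels cluster), rate variation
across sites, phylogenetic correlation between sequences, and alignment
errors. Passing tests therefore certify the algebra of the pipeline —
construction, conservation, geometry, determinism — on alignments of
realistic shape, not biological plausibility of any particular picture.

Test problem sizes: round trips run on 200 alignments up to 30 × 120 with
gap rates to 0.3; the consensus oracle on >3000 graphs up to 4 × 6;
geometry on 50 layouts up to 15 × 50; and one large run of 30 × 800 at
high divergence (≈12k nodes, ≈23k links) exercises layout and rendering
at the scale of the biggest graphs the tool targets.

## Degenerate inputs and edge behavior

- Empty files, ragged rows, duplicate ids, all-gap rows: rejected with
  the offender named.
- A single-sequence alignment is valid; its consensus is its own path.
- A single-column range is centered horizontally.
- A canvas too small to fit the fullest column's gaps fails loudly
  rather than producing negative flow units.
- `--simplify` on nucleotide input without a custom grouping is an error,
  not a silent no-op: every standard base would land in `other` and the
  picture would quietly become meaningless.

## Known limitations

- The package visualizes existing alignments; it neither aligns
  sequences nor threads new sequences into a graph.
- Barycenter ordering is a heuristic; pathological graphs can still show
  avoidable crossings (manual `y_overrides` are the escape hatch).
- The matrix panel renders every cell; for very wide alignments the SVG
  grows linearly (tooltips and in-cell letters can be disabled, and
  column ranges keep working views small).
- Cyclic/bidirected rendering exists at the geometry level only; there
  is no importer that produces such graphs.
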