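Package: poaflow
Title: Partial Order Alignment Graphs as Sankey Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds partial order alignment (POA) graphs from multiple
    sequence alignments in FASTA, Clustal, MSF, Phylip or Stockholm format
    and renders them as column-constrained Sankey diagrams with
    flow-proportional geometry. Within each alignment column, identical
    residues are merged into one node and every sequence traces a path
    through the resulting DAG. The package can simplify protein graphs by
    physicochemical residue class, compute a maximum-support consensus path,
    highlight sequence subsets selected by sequence, clade or node toggles,
    and emit deterministic SVG with synchronized Sankey, alignment-matrix
    and phylogenetic-tree panels. Includes a seeded generator of gapped
    alignments and random trees for testing, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
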