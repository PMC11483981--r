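# Graph construction, reconstruction, grouping, simplification, consensus.

test_that("build_poa merges identical residues and splits variants", {
  g <- build_poa(new_alignment(c("a", "b", "c"), c("AC", "AC", "AC")))
  expect_identical(g$nodes$node_id, c("0/A", "1/C"))
  expect_identical(g$nodes$members, list(`0/A` = 0:2, `1/C` = 0:2))
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$members[[1]], 0:2)

  g2 <- build_poa(new_alignment(c("a", "b"), c("AC", "AG")))
  expect_identical(g2$nodes$node_id, c("0/A", "1/C", "1/G"))
  expect_identical(g2$edges$src, c("0/A", "0/A"))
  expect_setequal(g2$edges$dst, c("1/C", "1/G"))
})

test_that("gap columns produce long edges spanning them", {
  g <- build_poa(new_alignment(c("a", "b"), c("A-C", "ABC")))
  expect_setequal(g$nodes$node_id, c("0/A", "1/B", "2/C"))
  long <- g$edges[g$edges$src == "0/A" & g$edges$dst == "2/C", ]
  expect_identical(nrow(long), 1L)
  expect_identical(long$members[[1]], 0L)
})

test_that("node count per column equals distinct non-gap symbols", {
  for (seed in 1:10) {
    a <- random_fixture(seed)
    g <- build_poa(a)
    m <- alignment_matrix(a)
    expected <- apply(m, 2, function(col)
      length(unique(col[col != "-"])))
    got <- tabulate(g$nodes$column + 1L, nbins = a$n_columns)
    expect_identical(got, as.integer(expected), info = seed)
  }
})

test_that("reconstruction inverts construction on random alignments", {
  for (seed in 1:40) {
    a <- random_fixture(seed, max_seqs = 15, max_cols = 60)
    expect_true(reconstruct_alignment(build_poa(a)) == a, info = seed)
  }
})

test_that("a broken sequence path is a structural-integrity error", {
  g <- build_poa(new_alignment(c("a", "b"), c("ACT", "AGT")))
  g$edges <- g$edges[-1, ]
  expect_error(reconstruct_alignment(g), regexp = "structural integrity")
})

test_that("edge spans cross only gap columns for their member sequences", {
  for (seed in 1:10) {
    a <- random_fixture(seed, max_seqs = 10, max_cols = 40, max_gap = 0.3)
    g <- build_poa(a)
    m <- alignment_matrix(a)
    scol <- as.integer(sub("/.*", "", g$edges$src))
    dcol <- as.integer(sub("/.*", "", g$edges$dst))
    expect_true(all(scol < dcol), info = seed)
    for (i in which(dcol - scol > 1)) {
      inner <- m[g$edges$members[[i]] + 1L,
                 (scol[i] + 2):(dcol[i]), drop = FALSE]
      expect_true(all(inner == "-"), info = sprintf("seed %d edge %d",
                                                    seed, i))
    }
  }
})

test_that("default grouping covers the 20 amino acids with four classes", {
  grp <- default_grouping()
  expect_identical(group_of("K"), "electrically charged")
  expect_identical(group_of("L"), "hydrophobic")
  expect_identical(group_of("S"), "polar uncharged")
  expect_identical(group_of("G"), "special")
  expect_identical(group_of("X"), "other")
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  expect_true(all(aas %in% names(grp$mapping)))
  expect_identical(sort(unique(unname(grp$mapping))),
                   sort(c("electrically charged", "polar uncharged",
                          "hydrophobic", "special")))
})

test_that("simplification merges same-group nodes and conserves membership", {
  a <- new_alignment(c("a", "b"), c("VD", "LE"))
  gs <- simplify_poa(build_poa(a))
  expect_identical(gs$nodes$node_id,
                   c("0/hydrophobic", "1/electrically charged"))
  expect_identical(gs$nodes$members[[1]], 0:1)
  expect_identical(nrow(gs$edges), 1L)
  expect_identical(gs$edges$members[[1]], 0:1)
})

test_that("identity grouping leaves the graph unchanged", {
  g <- build_poa(generate_msa_fixture(8, 25, "protein", 0.4, 0.1, seed = 5))
  gi <- simplify_poa(g, identity_grouping())
  expect_identical(gi$nodes$node_id, g$nodes$node_id)
  expect_identical(unname(gi$nodes$members), unname(g$nodes$members))
  expect_identical(gi$edges$src, g$edges$src)
  expect_identical(gi$edges$dst, g$edges$dst)
  expect_identical(unname(gi$edges$members), unname(g$edges$members))
})

test_that("simplification is idempotent and respects the group-label view", {
  for (seed in 1:10) {
    a <- generate_msa_fixture(10, 30, "protein", 0.5, 0.15, seed = seed)
    g <- build_poa(a)
    gs <- simplify_poa(g)
    gss <- simplify_poa(gs)
    expect_identical(gs$nodes$node_id, gss$nodes$node_id, info = seed)
    expect_identical(unname(gs$nodes$members), unname(gss$nodes$members))
    # per-column membership conserved, at most 5 groups per column
    for (cc in unique(g$nodes$column)) {
      before <- sort(unname(unlist(g$nodes$members[g$nodes$column == cc])))
      after <- sort(unname(unlist(gs$nodes$members[gs$nodes$column == cc])))
      expect_identical(after, before)
      expect_lte(sum(gs$nodes$column == cc), 5)
    }
    # the label matrix equals the row-wise symbol -> group mapping
    lm <- reconstruct_matrix(gs)
    expected <- alignment_matrix(a)
    expected[expected != "-"] <- group_of(expected[expected != "-"])
    dimnames(lm) <- dimnames(expected)
    expect_identical(lm, expected, info = seed)
  }
})

test_that("consensus matches exhaustive enumeration on small random graphs", {
  for (seed in 1:25) {
    set.seed(seed)
    a <- random_tiny_aln(sample(2:6, 1), sample(2:10, 1))
    g <- build_poa(a)
    got <- consensus_path(g)
    expect_equal(got$weight, brute_consensus_weight(g, a), info = seed)
    # the reported weight is realized by the reported path
    expect_identical(got$path, consensus_path(g)$path, info = seed)
  }
})

test_that("consensus of a single sequence is its full path", {
  a <- new_alignment("only", "AC-GT")
  got <- consensus_path(build_poa(a))
  expect_identical(got$path, c("0/A", "1/C", "3/G", "4/T"))
  expect_equal(got$weight, 1 + 3 + 1)  # start + three edges + end
})

test_that("equal-weight alternatives resolve to the smaller symbol", {
  # two sequences diverge at column 1 with equal support; 'A' beats 'G'
  a <- new_alignment(c("x", "y"), c("CAT", "CGT"))
  got <- consensus_path(build_poa(a))
  expect_identical(got$path, c("0/C", "1/A", "2/T"))
})

test_that("node membership lookup returns indices and ids", {
  g <- build_poa(new_alignment(c("id0", "id1"), c("AC", "AG")))
  expect_identical(node_sequences(g, "0/A"),
                   list(indices = 0:1, ids = c("id0", "id1")))
  expect_identical(node_sequences(g, "1/G")$ids, "id1")
  expect_error(node_sequences(g, "9/Z"), class = "poaflow_input_error")
})

test_that("graph JSON export/import round trips", {
  g <- build_poa(generate_msa_fixture(6, 15, "nucleotide", 0.3, 0.2,
                                      seed = 77))
  g2 <- poa_from_json(poa_to_json(g))
  expect_identical(g2$nodes$node_id, g$nodes$node_id)
  expect_identical(unname(g2$nodes$members), unname(g$nodes$members))
  expect_identical(g2$edges$src, g$edges$src)
  expect_identical(unname(g2$edges$members), unname(g$edges$members))
  expect_identical(g2$ids, g$ids)
  expect_true(reconstruct_alignment(g2) == reconstruct_alignment(g))
})
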