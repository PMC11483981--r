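# Shared fixtures and independent oracles. The oracles deliberately avoid
# the code paths they check: consensus weight comes from exhaustive path
# enumeration, flow bookkeeping from the raw alignment matrix.

tiny_aln <- function() new_alignment(c("a", "b", "c"),
                                     c("AC-TGGTA", "ACGTG-TA", "AC-TGCTA"))

random_fixture <- function(seed, max_seqs = 30, max_cols = 120,
                           max_gap = 0.3, max_sub = 0.5) {
  set.seed(seed)
  n <- sample(2:max_seqs, 1)
  L <- sample(2:max_cols, 1)
  alpha <- sample(c("nucleotide", "protein"), 1)
  generate_msa_fixture(n, L, alpha,
                       substitution_rate = stats::runif(1, 0, max_sub),
                       gap_rate = stats::runif(1, 0, max_gap),
                       seed = seed + 1000L)
}

# exhaustive maximum source-to-sink path weight; start/end weights are
# recomputed from the alignment rows, edge weights enumerated by DFS
brute_consensus_weight <- function(g, aln) {
  m <- alignment_matrix(aln)
  firsts <- apply(m, 1, function(r) which(r != "-")[1])
  lasts <- apply(m, 1, function(r) max(which(r != "-")))
  start_id <- paste0(firsts - 1L, "/", m[cbind(seq_len(nrow(m)), firsts)])
  end_id <- paste0(lasts - 1L, "/", m[cbind(seq_len(nrow(m)), lasts)])
  starts <- table(start_id)
  ends <- table(end_id)
  ew <- unname(lengths(g$edges$members))
  out_of <- split(seq_len(nrow(g$edges)), g$edges$src)
  best <- -Inf
  dfs <- function(node, acc) {
    e_here <- ends[node]
    if (!is.na(e_here)) {
      tot <- acc + as.numeric(e_here)
      if (tot > best) best <<- tot
    }
    for (ei in out_of[[node]]) dfs(g$edges$dst[ei], acc + ew[ei])
  }
  for (s in names(starts)) dfs(s, as.numeric(starts[s]))
  best
}

# flow conservation at every node, computed from the alignment rows
check_flow_conservation <- function(g, aln) {
  m <- alignment_matrix(aln)
  firsts <- apply(m, 1, function(r) which(r != "-")[1])
  lasts <- apply(m, 1, function(r) max(which(r != "-")))
  start_id <- paste0(firsts - 1L, "/", m[cbind(seq_len(nrow(m)), firsts)])
  end_id <- paste0(lasts - 1L, "/", m[cbind(seq_len(nrow(m)), lasts)])
  ew <- lengths(g$edges$members)
  inc <- tapply(ew, g$edges$dst, sum)
  out <- tapply(ew, g$edges$src, sum)
  for (i in seq_len(nrow(g$nodes))) {
    id <- g$nodes$node_id[i]
    cnt <- length(g$nodes$members[[i]])
    got_in <- sum(inc[id], na.rm = TRUE) + sum(start_id == id)
    got_out <- sum(out[id], na.rm = TRUE) + sum(end_id == id)
    if (got_in != cnt || got_out != cnt) return(FALSE)
  }
  TRUE
}

# uniformly random tiny alignment over {A, C, -}, rejecting all-gap
# rows/columns (used with the brute-force consensus oracle)
random_tiny_aln <- function(n_seqs, n_cols) {
  repeat {
    m <- matrix(sample(c("A", "C", "-"), n_seqs * n_cols, replace = TRUE),
                nrow = n_seqs)
    if (all(rowSums(m != "-") > 0) && all(colSums(m != "-") > 0)) {
      return(new_alignment(paste0("s", seq_len(n_seqs)),
                           apply(m, 1, paste, collapse = "")))
    }
  }
}

# all n_seqs x n_cols alignments over {A, C, -} with no all-gap row/column
enumerate_tiny_alns <- function(n_seqs, n_cols) {
  syms <- c("A", "C", "-")
  cells <- n_seqs * n_cols
  grid <- do.call(expand.grid,
                  c(rep(list(syms), cells), stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    m <- matrix(unlist(grid[i, ]), nrow = n_seqs)
    if (all(rowSums(m != "-") > 0) && all(colSums(m != "-") > 0)) {
      out[[length(out) + 1]] <-
        new_alignment(paste0("s", seq_len(n_seqs)),
                      apply(m, 1, paste, collapse = ""))
    }
  }
  out
}

# node rectangles of one column must not overlap; link thicknesses must
# tile each node side contiguously (counts compared exactly, coordinates
# to float precision)
check_layout_geometry <- function(g, lay) {
  pl <- lay$placements
  u <- lay$flow_unit
  for (cix in split(seq_len(nrow(pl)), pl$column)) {
    if (length(cix) < 2) next
    o <- cix[order(pl$y[cix])]
    tops <- pl$y[o]
    bots <- pl$y[o] + pl$height[o]
    if (any(tops[-1] < bots[-length(bots)] - 1e-9)) return("overlap")
  }
  lk <- lay$links
  for (i in seq_len(nrow(pl))) {
    id <- pl$node_id[i]
    for (side in c("src", "dst")) {
      li <- which(lk[[side]] == id &
                    lk$shape != paste0("stub_", if (side == "src") "left" else "right"))
      li <- li[!is.na(lk$x0[li])]
      if (length(li) == 0) next
      anchor_y <- if (side == "src") lk$y0[li] else lk$y1[li]
      o <- li[order(anchor_y)]
      ys <- sort(anchor_y)
      th <- lk$thickness[o]
      if (abs(ys[1] - pl$y[i]) > 1e-9) return("tiling-top")
      if (length(o) > 1 &&
          any(abs(ys[-1] - (ys[-length(ys)] + th[-length(th)])) > 1e-9))
        return("tiling-contiguity")
      # exact conservation in flow units: attached member counts
      cont <- sum(lk$thickness[o]) / u
      expected <- sum(lengths(lk$members[o]))
      if (!isTRUE(all.equal(cont, expected, tolerance = 1e-12)))
        return("tiling-units")
      if (sum(lk$thickness[o]) > pl$height[i] + 1e-9) return("tiling-height")
    }
  }
  "ok"
}
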