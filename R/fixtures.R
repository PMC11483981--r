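# Seeded generators of gapped alignments and random trees. These define
# the study conditions of the test suite: an ancestral row mutated by
# per-column substitution plus independent gap insertion emulates a family
# of homologous sequences at a chosen divergence; it does not emulate
# indel blocks, rate heterogeneity across sites, or phylogenetic
# correlation between rows.

NUC_SYMBOLS <- c("A", "C", "G", "T")
AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a random gapped alignment
#'
#' Draws a random ancestral row, then derives each sequence by per-column
#' substitution (probability `substitution_rate`, replacement drawn
#' uniformly from the alphabet) and independent gap insertion
#' (probability `gap_rate`). All-gap rows and all-gap columns are repaired
#' deterministically so the result always satisfies the alignment
#' invariants. Identical seeds give identical alignments; the caller's RNG
#' state is left untouched.
#'
#' @param n_seqs,n_columns Dimensions (`n_seqs >= 1`, `n_columns >= 1`).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param substitution_rate,gap_rate Per-position probabilities in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return A [new_alignment()] object with ids `s1..sN`.
#' @export
generate_msa_fixture <- function(n_seqs, n_columns,
                                 alphabet = c("nucleotide", "protein"),
                                 substitution_rate = 0.2, gap_rate = 0.1,
                                 seed = 1) {
  alphabet <- match.arg(alphabet)
  if (n_seqs < 1 || n_columns < 1)
    stop_input("n_seqs and n_columns must be >= 1")
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      gap_rate < 0 || gap_rate >= 1)
    stop_input("rates must lie in [0, 1)")
  syms <- if (alphabet == "nucleotide") NUC_SYMBOLS else AA_SYMBOLS
  with_seed(seed, {
    anc <- sample(syms, n_columns, replace = TRUE)
    m <- matrix(rep(anc, each = n_seqs), nrow = n_seqs)
    sub <- matrix(stats::runif(n_seqs * n_columns) < substitution_rate,
                  nrow = n_seqs)
    if (any(sub)) m[sub] <- sample(syms, sum(sub), replace = TRUE)
    gap <- matrix(stats::runif(n_seqs * n_columns) < gap_rate,
                  nrow = n_seqs)
    m[gap] <- "-"
    # repair all-gap columns first (restore the ancestor in one row),
    # then all-gap rows (cannot re-create an all-gap column)
    for (j in which(colSums(m != "-") == 0)) {
      m[sample.int(n_seqs, 1), j] <- anc[j]
    }
    for (i in which(rowSums(m != "-") == 0)) {
      j <- sample.int(n_columns, 1)
      m[i, j] <- anc[j]
    }
    new_alignment(paste0("s", seq_len(n_seqs)),
                  apply(m, 1, paste, collapse = ""),
                  alphabet = alphabet)
  })
}

#' Generate a random binary tree over given leaf ids
#'
#' Builds the tree by sequential random joins: starting from one cluster
#' per id, repeatedly joins two random clusters until one remains. Unit
#' branch lengths. Deterministic under the seed.
#'
#' @param ids Character vector of at least two leaf labels.
#' @param seed Integer seed.
#' @return An `ape` `phylo` tree with exactly these leaves.
#' @export
generate_tree_fixture <- function(ids, seed = 1) {
  ids <- as.character(ids)
  if (length(ids) < 2) stop_input("need at least 2 ids for a tree")
  with_seed(seed, {
    clusters <- as.list(ids)
    while (length(clusters) > 1) {
      pick <- sample.int(length(clusters), 2)
      joined <- sprintf("(%s:1,%s:1)", clusters[[pick[1]]],
                        clusters[[pick[2]]])
      clusters <- c(clusters[-pick], joined)
    }
    read_newick(paste0(clusters[[1]], ";"))
  })
}
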