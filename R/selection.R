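# Highlighted-sequence state shared by all render panels. Three toggle
# actions mutate it: per-sequence, per-clade, per-node. Group toggles use
# the "add unless already fully selected" rule so both branches are
# reachable and double application is an involution.

#' Create an empty selection state
#'
#' @param n_sequences Number of sequences selectable (indices
#'   `0..n_sequences-1`).
#' @return A `selection_state`: list with `selected` (sorted 0-based
#'   integer vector), `history` (character vector of applied actions) and
#'   `n_sequences`.
#' @export
new_selection <- function(n_sequences) {
  if (n_sequences < 0) stop_input("negative sequence count")
  structure(list(selected = integer(0), history = character(0),
                 n_sequences = as.integer(n_sequences)),
            class = "selection_state")
}

#' @noRd
apply_set_toggle <- function(state, set, action) {
  set <- sort(unique(as.integer(set)))
  if (length(set) && all(set %in% state$selected)) {
    state$selected <- setdiff(state$selected, set)
  } else {
    state$selected <- sort(union(state$selected, set))
  }
  state$history <- c(state$history, action)
  state
}

#' Toggle a single sequence
#'
#' Flips membership of one sequence in the highlighted set, as clicking a
#' sequence identifier would.
#'
#' @param state A [new_selection()] state.
#' @param seq_index 0-based sequence index.
#' @return The updated `selection_state`.
#' @export
toggle_sequence <- function(state, seq_index) {
  seq_index <- as.integer(seq_index)
  if (is.na(seq_index) || seq_index < 0 || seq_index >= state$n_sequences)
    stop_input("sequence index %s out of range 0..%d",
               as.character(seq_index), state$n_sequences - 1L)
  if (seq_index %in% state$selected) {
    state$selected <- setdiff(state$selected, seq_index)
  } else {
    state$selected <- sort(c(state$selected, seq_index))
  }
  state$history <- c(state$history, paste0("seq#", seq_index))
  state
}

#' Toggle all descendants of a tree node
#'
#' Clicking a vertex or branch of the phylogenetic tree toggles all its
#' descendant leaves: if every descendant is already selected they are all
#' removed, otherwise all are added.
#'
#' @param state A [new_selection()] state.
#' @param tree A `phylo` tree whose leaf labels are alignment identifiers.
#' @param tree_node A leaf label, an internal node label, or an ape node
#'   number.
#' @param ids Alignment identifiers defining sequence indices (leaf label
#'   `ids[i+1]` is sequence index `i`).
#' @return The updated `selection_state`.
#' @export
toggle_clade <- function(state, tree, tree_node, ids) {
  tips <- clade_tips(tree, tree_node)
  idx <- match(tips, ids) - 1L
  if (anyNA(idx))
    stop_input("tree leaves not present in alignment: %s",
               paste(tips[is.na(idx)], collapse = ", "))
  apply_set_toggle(state, idx, paste0("clade#", as.character(tree_node)))
}

# descendant leaf labels of a node given by label or ape node number
#' @noRd
clade_tips <- function(tree, tree_node) {
  ntip <- length(tree$tip.label)
  num <- NA_integer_
  if (is.numeric(tree_node)) {
    num <- as.integer(tree_node)
  } else if (tree_node %in% tree$tip.label) {
    num <- match(tree_node, tree$tip.label)
  } else if (!is.null(tree$node.label) && tree_node %in% tree$node.label) {
    num <- ntip + match(tree_node, tree$node.label)
  }
  if (is.na(num) || num < 1 || num > ntip + tree$Nnode)
    stop_input("unknown tree node: %s", as.character(tree_node))
  if (num <= ntip) return(tree$tip.label[num])
  desc <- num
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% desc, 2]
    nxt <- union(desc, kids)
    if (length(nxt) == length(desc)) break
    desc <- nxt
  }
  tree$tip.label[sort(desc[desc <= ntip])]
}

#' Toggle all sequences passing through a POA node
#'
#' @param state A [new_selection()] state.
#' @param g A `poa_graph`.
#' @param node_id Node identifier (`"column/symbol"`).
#' @return The updated `selection_state`.
#' @export
toggle_node <- function(state, g, node_id) {
  memb <- node_sequences(g, node_id)$indices
  apply_set_toggle(state, memb, paste0("node#", node_id))
}

#' Parse and apply one-line selection expressions
#'
#' Expressions use the syntax `seq:ID`, `clade:LABEL` and
#' `node:COL/SYMBOL` (0-based column as in node identifiers) and are
#' applied in order to an empty state.
#'
#' @param exprs Character vector of selection expressions.
#' @param g A `poa_graph`.
#' @param tree Optional `phylo` tree (required for `clade:` expressions).
#' @return The resulting `selection_state`.
#' @export
parse_selection <- function(exprs, g, tree = NULL) {
  state <- new_selection(g$n_sequences)
  for (e in exprs) {
    kind <- sub(":.*$", "", e)
    arg <- sub("^[a-z]+:", "", e)
    state <- switch(kind,
      seq = {
        i <- match(arg, g$ids)
        if (is.na(i)) stop_input("unknown sequence id in selection: %s", arg)
        toggle_sequence(state, i - 1L)
      },
      clade = {
        if (is.null(tree))
          stop_input("selection '%s' needs a tree", e)
        toggle_clade(state, tree, arg, g$ids)
      },
      node = toggle_node(state, g, arg),
      stop_input("unparseable selection expression: %s", e))
  }
  state
}

#' @export
print.selection_state <- function(x, ...) {
  cat(sprintf("<selection_state> %d/%d selected: %s\n",
              length(x$selected), x$n_sequences,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
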