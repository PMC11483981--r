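# Partial order alignment graph: one node per (column, distinct non-gap
# symbol), members = the sequences showing that symbol there; one merged
# edge per ordered pair of consecutive non-gap positions of any sequence.
# Gap stretches produce "long" edges spanning more than one column.
#
# Node identifiers are "column/symbol" strings with 0-based columns, so they
# are stable across runs and need no hidden counters.

#' @noRd
node_id_of <- function(column, symbol) paste0(column, "/", symbol)

#' Build a POA graph from an alignment
#'
#' Within each alignment column, identical residues are merged into a
#' single node whose members are the sequences carrying that residue;
#' directed edges connect consecutive non-gap positions of every sequence,
#' with parallel per-sequence edges between the same node pair merged and
#' their member sets unioned. Every sequence then traces a path through the
#' resulting column-ordered DAG.
#'
#' @param aln A [new_alignment()] object.
#' @return A `poa_graph`: list with `n_columns`, `n_sequences`, `ids`,
#'   `alphabet`, a `nodes` data frame (`node_id`, `column`, `symbol`,
#'   list-column `members` of 0-based sequence indices) and an `edges` data
#'   frame (`src`, `dst`, `members`).
#' @examples
#' g <- build_poa(new_alignment(c("a", "b"), c("AC", "AG")))
#' g$nodes$node_id
#' @export
build_poa <- function(aln) {
  m <- alignment_matrix(aln)
  nseq <- nrow(m)
  hit <- which(m != "-", arr.ind = TRUE)
  col0 <- hit[, "col"] - 1L
  sym <- m[hit]
  nid <- node_id_of(col0, sym)
  memb <- split(hit[, "row"] - 1L, nid)
  # deterministic node order: by column, then symbol
  uid <- names(memb)
  usplit <- strsplit(uid, "/", fixed = TRUE)
  ucol <- as.integer(vapply(usplit, `[`, character(1), 1))
  usym <- vapply(usplit, `[`, character(1), 2)
  ord <- order(ucol, usym)
  nodes <- data.frame(node_id = uid[ord], column = ucol[ord],
                      symbol = usym[ord], stringsAsFactors = FALSE)
  nodes$members <- lapply(memb[ord], function(v) sort(unname(v)))

  # per-sequence consecutive non-gap positions -> edge instances
  esrc <- character(0); edst <- character(0); eseq <- integer(0)
  for (s in seq_len(nseq)) {
    nz <- which(m[s, ] != "-")
    if (length(nz) < 2) next
    pid <- node_id_of(nz - 1L, m[s, nz])
    esrc <- c(esrc, pid[-length(pid)])
    edst <- c(edst, pid[-1])
    eseq <- c(eseq, rep.int(s - 1L, length(pid) - 1L))
  }
  if (length(esrc)) {
    ekey <- paste(esrc, edst, sep = ">")
    emem <- split(eseq, ekey)
    ukey <- names(emem)
    parts <- strsplit(ukey, ">", fixed = TRUE)
    src <- vapply(parts, `[`, character(1), 1)
    dst <- vapply(parts, `[`, character(1), 2)
    scol <- as.integer(sub("/.*", "", src))
    dcol <- as.integer(sub("/.*", "", dst))
    eord <- order(scol, dcol, src, dst)
    edges <- data.frame(src = src[eord], dst = dst[eord],
                        stringsAsFactors = FALSE)
    edges$members <- lapply(emem[eord], function(v) sort(unname(v)))
  } else {
    edges <- data.frame(src = character(0), dst = character(0),
                        stringsAsFactors = FALSE)
    edges$members <- list()
  }
  structure(list(n_columns = aln$n_columns, n_sequences = nseq,
                 ids = aln$ids, alphabet = aln$alphabet,
                 nodes = nodes, edges = edges),
            class = "poa_graph")
}

#' @export
print.poa_graph <- function(x, ...) {
  cat(sprintf("<poa_graph> %d columns, %d sequences, %d nodes, %d edges (%s)\n",
              x$n_columns, x$n_sequences, nrow(x$nodes), nrow(x$edges),
              x$alphabet))
  invisible(x)
}

#' @noRd
node_column <- function(node_id) as.integer(sub("/.*", "", node_id))

#' @noRd
node_symbol <- function(node_id) sub("^[0-9]+/", "", node_id)

#' Rebuild the alignment encoded by a POA graph
#'
#' The inverse of [build_poa()]: each sequence's row carries the node
#' symbol at every column whose node contains the sequence and a gap
#' elsewhere. The edge set is verified on the way: for every sequence the
#' nodes containing it, taken in column order, must be connected by edges
#' that also contain it.
#'
#' @param g A `poa_graph`.
#' @return A [new_alignment()] object.
#' @export
reconstruct_alignment <- function(g) {
  m <- reconstruct_matrix(g)
  # structural check: consecutive nodes of every sequence are edge-linked
  have <- unlist(lapply(seq_len(nrow(g$edges)), function(i) {
    paste(g$edges$src[i], g$edges$dst[i], g$edges$members[[i]], sep = "|")
  }))
  for (s in seq_len(g$n_sequences)) {
    nz <- which(m[s, ] != "-")
    if (length(nz) < 2) next
    pid <- node_id_of(nz - 1L, m[s, nz])
    need <- paste(pid[-length(pid)], pid[-1], s - 1L, sep = "|")
    missing <- need[!need %in% have]
    if (length(missing))
      stop_internal(
        "structural integrity violation: sequence %s has no edge %s",
        g$ids[s], strsplit(missing[1], "|", fixed = TRUE)[[1]][1])
  }
  new_alignment(g$ids, apply(m, 1, paste, collapse = ""),
                alphabet = g$alphabet)
}

#' Per-cell symbol matrix encoded by a POA graph
#'
#' Like [reconstruct_alignment()] but without the row-string validation,
#' so it also works for simplified graphs whose symbols are multi-character
#' group labels.
#'
#' @param g A `poa_graph`.
#' @return Character matrix (sequences x columns) of symbols/labels, `"-"`
#'   for gaps.
#' @export
reconstruct_matrix <- function(g) {
  m <- matrix("-", nrow = g$n_sequences, ncol = g$n_columns)
  ncol_n <- g$nodes$column
  nsym <- g$nodes$symbol
  nmem <- g$nodes$members
  for (i in seq_along(ncol_n)) {
    m[nmem[[i]] + 1L, ncol_n[i] + 1L] <- nsym[i]
  }
  rownames(m) <- g$ids
  m
}

#' Sequences passing through a node
#'
#' @param g A `poa_graph`.
#' @param node_id A node identifier (`"column/symbol"`, 0-based column).
#' @return List with `indices` (0-based) and `ids` (identifier strings).
#' @export
node_sequences <- function(g, node_id) {
  i <- match(node_id, g$nodes$node_id)
  if (is.na(i)) stop_input("unknown node id: %s", node_id)
  idx <- g$nodes$members[[i]]
  list(indices = idx, ids = g$ids[idx + 1L])
}

# --- residue grouping ----------------------------------------------------

#' Default physicochemical residue grouping
#'
#' Partitions the 20 standard amino acids into four classes — electrically
#' charged, polar uncharged, hydrophobic, and special cases — used to
#' simplify protein POA graphs. Any unmapped symbol (ambiguity codes,
#' nonstandard residues) falls into group `"other"`. The class memberships
#' follow the common physicochemical side-chain classification and can be
#' replaced wholesale via [residue_grouping()].
#'
#' @return A `residue_grouping` object.
#' @examples
#' default_grouping()$mapping[["K"]]
#' @export
default_grouping <- function() {
  residue_grouping(list(
    "electrically charged" = c("D", "E", "K", "R", "H"),
    "polar uncharged"      = c("S", "T", "N", "Q", "Y"),
    "hydrophobic"          = c("A", "V", "L", "I", "M", "F", "W"),
    "special"              = c("C", "G", "P")
  ), name = "physicochemical-4")
}

#' Construct a residue grouping scheme
#'
#' @param groups Named list: group label -> character vector of residue
#'   symbols. Symbols are upper-cased; each symbol may appear in one group.
#' @param name Scheme identifier.
#' @return A `residue_grouping`: list with a `mapping` named vector
#'   (symbol -> group label) and `name`. Unmapped symbols resolve to
#'   `"other"` via [group_of()].
#' @export
residue_grouping <- function(groups, name = "custom") {
  syms <- toupper(unlist(groups, use.names = FALSE))
  dup <- unique(syms[duplicated(syms)])
  if (length(dup))
    stop_input("symbols assigned to more than one group: %s",
               paste(dup, collapse = ", "))
  mapping <- stats::setNames(
    rep(names(groups), lengths(groups)), syms)
  structure(list(mapping = mapping, name = name),
            class = "residue_grouping")
}

#' Identity grouping (each symbol is its own group)
#' @param symbols Symbols to map to themselves.
#' @return A `residue_grouping`.
#' @export
identity_grouping <- function(symbols = LETTERS) {
  residue_grouping(stats::setNames(as.list(symbols), symbols),
                   name = "identity")
}

#' Map residue symbols to their group labels
#' @param symbols Character vector of residue symbols.
#' @param grouping A `residue_grouping`.
#' @return Character vector of group labels; unmapped symbols give
#'   `"other"`.
#' @export
group_of <- function(symbols, grouping = default_grouping()) {
  out <- unname(grouping$mapping[toupper(symbols)])
  out[is.na(out)] <- "other"
  out
}

#' Simplify a POA graph by residue grouping
#'
#' Within each column, nodes whose symbols map to the same group label are
#' merged into a single node labeled by the group, member sets unioned;
#' edges are re-derived between the merged nodes. Per-column membership is
#' conserved and the operation is idempotent (group labels map to
#' themselves under [group_of()]'s `"other"` fallback only if re-applied
#' with an identity grouping over labels, so idempotence is guaranteed by
#' mapping already-merged labels onto themselves).
#'
#' @param g A `poa_graph`.
#' @param grouping A `residue_grouping`; defaults to the four
#'   physicochemical classes.
#' @return A `poa_graph` whose node symbols are group labels.
#' @export
simplify_poa <- function(g, grouping = default_grouping()) {
  labels <- unique(c(grouping$mapping, "other"))
  map_sym <- function(s) ifelse(s %in% labels, s, group_of(s, grouping))
  new_sym <- map_sym(g$nodes$symbol)
  new_id <- node_id_of(g$nodes$column, new_sym)
  remap <- stats::setNames(new_id, g$nodes$node_id)

  memb <- lapply(split(g$nodes$members, new_id),
                 function(l) sort(unique(unlist(l))))
  uid <- names(memb)
  ucol <- node_column(uid)
  usym <- node_symbol(uid)
  ord <- order(ucol, usym)
  nodes <- data.frame(node_id = uid[ord], column = ucol[ord],
                      symbol = usym[ord], stringsAsFactors = FALSE)
  nodes$members <- memb[ord]

  if (nrow(g$edges)) {
    esrc <- unname(remap[g$edges$src])
    edst <- unname(remap[g$edges$dst])
    ekey <- paste(esrc, edst, sep = ">")
    emem <- lapply(split(g$edges$members, ekey),
                   function(l) sort(unique(unlist(l))))
    parts <- strsplit(names(emem), ">", fixed = TRUE)
    src <- vapply(parts, `[`, character(1), 1)
    dst <- vapply(parts, `[`, character(1), 2)
    eord <- order(node_column(src), node_column(dst), src, dst)
    edges <- data.frame(src = src[eord], dst = dst[eord],
                        stringsAsFactors = FALSE)
    edges$members <- emem[eord]
  } else {
    edges <- g$edges
  }
  structure(list(n_columns = g$n_columns, n_sequences = g$n_sequences,
                 ids = g$ids, alphabet = g$alphabet,
                 nodes = nodes, edges = edges),
            class = "poa_graph")
}

# --- flow bookkeeping ----------------------------------------------------

# per-node counts of sequences starting/ending at the node, derived from
# flow conservation: starts = |members| - sum of incoming edge members
#' @noRd
node_flow <- function(g) {
  n <- nrow(g$nodes)
  cnt <- lengths(g$nodes$members)
  inc <- numeric(n)
  out <- numeric(n)
  if (nrow(g$edges)) {
    ew <- lengths(g$edges$members)
    di <- match(g$edges$dst, g$nodes$node_id)
    si <- match(g$edges$src, g$nodes$node_id)
    inc <- as.numeric(tabulate_weighted(di, ew, n))
    out <- as.numeric(tabulate_weighted(si, ew, n))
  }
  data.frame(node_id = g$nodes$node_id, column = g$nodes$column,
             symbol = g$nodes$symbol, count = cnt,
             incoming = inc, outgoing = out,
             starts = cnt - inc, ends = cnt - out,
             stringsAsFactors = FALSE)
}

# weighted bin counts: sum of w over entries falling in each bin 1..n
#' @noRd
tabulate_weighted <- function(bin, w, n) {
  v <- numeric(n)
  s <- tapply(w, bin, sum)
  v[as.integer(names(s))] <- s
  v
}

#' Consensus path through a POA graph
#'
#' Finds the source-to-sink path maximizing cumulative sequence support: a
#' virtual start (end) connects to every node where at least one sequence
#' starts (ends), with weight equal to the number of sequences starting
#' (ending) there, and each graph edge contributes its member count. The
#' maximizing path is computed by a dynamic-programming sweep over the
#' column-ordered DAG; ties are resolved deterministically at the earliest
#' divergence, preferring the node with more members, then the
#' lexicographically smaller symbol. Support is counted per edge (each
#' traversed transition contributes the sequences taking it), which mirrors
#' common POA consensus practice.
#'
#' @param g A non-empty `poa_graph`.
#' @return List with `path` (node ids in column order) and `weight` (total
#'   support).
#' @export
consensus_path <- function(g) {
  if (nrow(g$nodes) == 0) stop_input("empty graph has no consensus path")
  fl <- node_flow(g)
  n <- nrow(fl)
  idx <- stats::setNames(seq_len(n), fl$node_id)
  ew <- lengths(g$edges$members)
  si <- match(g$edges$src, g$nodes$node_id)
  out_by_src <- split(seq_len(nrow(g$edges)), factor(si, levels = seq_len(n)))

  # suffix DP in reverse column order: best achievable weight from each
  # node to the virtual end (including the final end weight)
  best_after <- rep(-Inf, n)
  ord <- order(fl$column, fl$symbol)
  for (i in rev(ord)) {
    v <- if (fl$ends[i] > 0) fl$ends[i] else -Inf
    for (e in out_by_src[[i]]) {
      cand <- ew[e] + best_after[idx[g$edges$dst[e]]]
      if (cand > v) v <- cand
    }
    best_after[i] <- v
  }

  # forward greedy walk; deciding at the earliest divergence makes the
  # stated tie-break (member count, then symbol) apply where paths differ
  pick <- function(cands) {
    # cands: data.frame(node_idx, value); best value, then more members,
    # then smaller symbol, then smaller column
    o <- order(-cands$value, -fl$count[cands$node_idx],
               fl$symbol[cands$node_idx], fl$column[cands$node_idx])
    cands[o[1], ]
  }
  startable <- which(fl$starts > 0 & is.finite(best_after))
  if (length(startable) == 0)
    stop_internal("no source-to-sink path found")
  first <- pick(data.frame(node_idx = startable,
                           value = fl$starts[startable] +
                             best_after[startable]))
  total <- first$value
  cur <- first$node_idx
  path <- fl$node_id[cur]
  repeat {
    eis <- out_by_src[[cur]]
    stop_v <- if (fl$ends[cur] > 0) fl$ends[cur] else -Inf
    if (length(eis) == 0) break
    cand <- data.frame(
      node_idx = idx[g$edges$dst[eis]],
      value = ew[eis] + best_after[idx[g$edges$dst[eis]]])
    nxt <- pick(cand)
    if (stop_v > nxt$value) break
    cur <- nxt$node_idx
    path <- c(path, fl$node_id[cur])
  }
  list(path = path, weight = unname(total))
}
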