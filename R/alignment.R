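#' Multiple sequence alignment container
#'
#' An `poa_alignment` is a rectangular matrix of residue/gap symbols stored
#' as one string per sequence, with ordered unique identifiers and an
#' alphabet tag. Sequence order as encountered in the input file defines the
#' 0-based sequence indices used by every downstream module.
#'
#' @param ids Character vector of unique, non-empty sequence identifiers.
#' @param rows Character vector of aligned sequences (same length strings),
#'   one per id. Symbols are upper-cased and `.` gaps normalized to `-`.
#' @param alphabet `"nucleotide"`, `"protein"`, or `NULL` to infer: the
#'   alignment is called nucleotide iff at least 95% of its non-gap symbols
#'   lie in `{A,C,G,T,U,N}`.
#' @return An object of class `poa_alignment` with fields `ids`, `rows`,
#'   `n_columns` and `alphabet`.
#' @examples
#' new_alignment(c("s1", "s2"), c("AC-T", "ACGT"))
#' @export
new_alignment <- function(ids, rows, alphabet = NULL) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  if (length(ids) != length(rows))
    stop_input("got %d ids but %d sequence rows", length(ids), length(rows))
  if (length(ids) == 0) stop_input("alignment has no sequences")
  if (any(!nzchar(ids))) stop_input("empty sequence identifier")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_input("duplicate sequence identifiers: %s",
               paste(dup, collapse = ", "))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1) {
    bad <- ids[lens != stats::median(lens)]
    stop_input("ragged alignment rows (lengths %s); offending ids: %s",
               paste(unique(lens), collapse = ", "),
               paste(bad, collapse = ", "))
  }
  n_columns <- lens[1]
  if (n_columns == 0) stop_input("alignment has zero columns")
  sym <- unique(strsplit(paste(rows, collapse = ""), "")[[1]])
  bad_sym <- setdiff(sym, c(LETTERS, "-", "*"))
  if (length(bad_sym))
    stop_input("illegal alignment symbols: %s", paste(bad_sym, collapse = " "))
  allgap <- vapply(rows, function(r) grepl("^-+$", r), logical(1))
  if (any(allgap))
    stop_input("rows consisting only of gaps: %s",
               paste(ids[allgap], collapse = ", "))
  if (is.null(alphabet)) alphabet <- infer_alphabet(rows)
  alphabet <- match.arg(alphabet, c("nucleotide", "protein"))
  structure(list(ids = ids, rows = rows, n_columns = n_columns,
                 alphabet = alphabet),
            class = "poa_alignment")
}

#' @noRd
infer_alphabet <- function(rows) {
  s <- strsplit(paste(rows, collapse = ""), "")[[1]]
  s <- s[s != "-"]
  if (length(s) == 0) return("nucleotide")
  if (mean(s %in% c("A", "C", "G", "T", "U", "N")) >= 0.95)
    "nucleotide" else "protein"
}

#' @export
print.poa_alignment <- function(x, ...) {
  cat(sprintf("<poa_alignment> %d sequences x %d columns (%s)\n",
              length(x$ids), x$n_columns, x$alphabet))
  show <- utils::head(seq_along(x$ids), 8)
  for (i in show) {
    r <- x$rows[i]
    if (nchar(r) > 60) r <- paste0(substr(r, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], r))
  }
  if (length(x$ids) > 8) cat(sprintf("  ... %d more\n", length(x$ids) - 8))
  invisible(x)
}

#' Character matrix view of an alignment
#' @param aln A [new_alignment()] object.
#' @return A character matrix, one row per sequence, one column per
#'   alignment column.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- aln$ids
  m
}

#' @export
`==.poa_alignment` <- function(e1, e2) {
  identical(e1$ids, e2$ids) && identical(e1$rows, e2$rows) &&
    identical(e1$alphabet, e2$alphabet)
}

#' Check that a tree's leaves match an alignment's identifiers
#'
#' The tree can only be displayed next to the alignment matrix when the two
#' describe exactly the same sequence set; any mismatch is rejected rather
#' than guessed around.
#'
#' @param tree A rooted `phylo` tree (see [read_newick()]).
#' @param aln A [new_alignment()] object.
#' @return `TRUE` invisibly on success.
#' @export
check_tree_alignment <- function(tree, aln) {
  leaves <- tree$tip.label
  miss_in_aln <- setdiff(leaves, aln$ids)
  miss_in_tree <- setdiff(aln$ids, leaves)
  if (length(miss_in_aln) || length(miss_in_tree)) {
    parts <- character(0)
    if (length(miss_in_aln))
      parts <- c(parts, sprintf("tree leaves absent from alignment: %s",
                                paste(miss_in_aln, collapse = ", ")))
    if (length(miss_in_tree))
      parts <- c(parts, sprintf("alignment ids absent from tree: %s",
                                paste(miss_in_tree, collapse = ", ")))
    stop_input("tree/alignment mismatch; %s", paste(parts, collapse = "; "))
  }
  invisible(TRUE)
}
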