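# Reading and writing alignments in the five supported formats.
#
# Format detection is signature-based and never guesses: each supported
# format is recognized by the first non-blank line. Parsing of FASTA,
# Phylip and Stockholm is delegated to Biostrings, MSF to seqinr; Clustal
# uses a small tolerant block parser because common dialects (single-block
# files, multi-block files without a padded conservation line) are not read
# consistently by either library.

MSA_FORMATS <- c("fasta", "clustal", "msf", "phylip", "stockholm")

#' Detect the alignment file format from its content
#'
#' @param text Raw file content (a character scalar, possibly multi-line).
#' @return One of `"fasta"`, `"clustal"`, `"msf"`, `"phylip"`,
#'   `"stockholm"`.
#' @examples
#' detect_format(">seq1\nACGT")
#' detect_format("# STOCKHOLM 1.0\nseq1 ACGT\n//")
#' @export
detect_format <- function(text) {
  text <- source_text(text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  nb <- lines[trimws(lines) != ""]
  if (length(nb) == 0) stop_input("empty alignment input")
  first <- trimws(nb[1])
  if (startsWith(first, ">")) return("fasta")
  if (grepl("^# STOCKHOLM", first)) return("stockholm")
  if (grepl("^CLUSTAL", toupper(first))) return("clustal")
  if (grepl("^(!!NA_MULTIPLE_ALIGNMENT|!!AA_MULTIPLE_ALIGNMENT|PILEUP)",
            toupper(first)) ||
      grepl("MSF:.*\\.\\.\\s*$", first))
    return("msf")
  if (grepl("^[0-9]+\\s+[0-9]+$", first)) return("phylip")
  stop_input("unrecognized alignment format; first line: %s", nb[1])
}

#' Read a multiple sequence alignment
#'
#' Accepts FASTA (aligned), Clustal, MSF, Phylip (relaxed or strict,
#' sequential or interleaved) and Stockholm input. Symbols are upper-cased
#' and `.` gaps normalized to `-` on read.
#'
#' @param source A file path, or the file content itself as a string.
#' @param format Optional format tag; when omitted, [detect_format()]
#'   decides from the content.
#' @param alphabet Optional `"nucleotide"`/`"protein"` override of the
#'   automatic alphabet inference.
#' @return A validated [new_alignment()] object.
#' @examples
#' read_alignment(">a\nAC-T\n>b\nACGT\n")
#' @export
read_alignment <- function(source, format = NULL, alphabet = NULL) {
  text <- source_text(source)
  if (!nzchar(trimws(text))) stop_input("empty alignment input")
  if (is.null(format)) format <- detect_format(text)
  format <- match.arg(format, MSA_FORMATS)
  parsed <- switch(format,
    fasta = parse_fasta(text),
    clustal = parse_clustal(text),
    msf = parse_msf(text),
    phylip = parse_phylip(text),
    stockholm = parse_stockholm(text))
  new_alignment(parsed$ids, parsed$rows, alphabet = alphabet)
}

# --- individual format parsers ------------------------------------------

#' @noRd
via_biostrings <- function(text, format, ext) {
  tf <- tempfile(fileext = ext)
  on.exit(unlink(tf))
  writeLines(text, tf)
  x <- tryCatch(
    Biostrings::readAAMultipleAlignment(tf, format = format),
    error = function(e) stop_input("%s parse failed: %s", format,
                                   conditionMessage(e)))
  rows <- as.character(x)
  list(ids = names(rows), rows = unname(rows))
}

#' @noRd
parse_fasta <- function(text) {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(text, tf)
  x <- tryCatch(Biostrings::readBStringSet(tf),
                error = function(e) stop_input("fasta parse failed: %s",
                                               conditionMessage(e)))
  # identifiers are the first whitespace-delimited token of the header
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  list(ids = ids, rows = as.character(unname(x)))
}

#' @noRd
parse_clustal <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!grepl("^CLUSTAL", toupper(trimws(lines[1]))))
    stop_input("clustal parse failed: missing CLUSTAL header")
  body <- lines[-1]
  seqs <- list()
  order <- character(0)
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    # conservation lines hold only *:. and spaces; skip them
    if (grepl("^[\\s*:.]+$", ln, perl = TRUE)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.\\-]+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (length(m) == 0)
      stop_input("clustal parse failed: unparseable line: %s", ln)
    nm <- m[2]; seg <- m[3]
    if (!nm %in% order) {
      order <- c(order, nm)
      seqs[[nm]] <- seg
    } else {
      seqs[[nm]] <- paste0(seqs[[nm]], seg)
    }
  }
  if (length(order) == 0) stop_input("clustal parse failed: no sequences")
  list(ids = order, rows = unlist(seqs[order], use.names = FALSE))
}

#' @noRd
parse_msf <- function(text) {
  tf <- tempfile(fileext = ".msf")
  on.exit(unlink(tf))
  writeLines(text, tf)
  x <- tryCatch(seqinr::read.alignment(tf, format = "msf"),
                error = function(e) stop_input("msf parse failed: %s",
                                               conditionMessage(e)))
  list(ids = x$nam, rows = unlist(x$seq, use.names = FALSE))
}

#' @noRd
parse_phylip <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  nb <- lines[trimws(lines) != ""]
  hdr <- regmatches(nb[1], regexec("^\\s*([0-9]+)\\s+([0-9]+)\\s*$", nb[1]))[[1]]
  if (length(hdr) == 0)
    stop_input("phylip parse failed: bad header line: %s", nb[1])
  nseq <- as.integer(hdr[2]); ncol <- as.integer(hdr[3])
  # relaxed (whitespace-delimited names) first
  relaxed <- tryCatch(via_biostrings(text, "phylip", ".phy"),
                      error = function(e) NULL)
  ok <- function(p) {
    !is.null(p) && length(p$ids) == nseq && all(nzchar(p$ids)) &&
      all(nchar(p$rows) == ncol)
  }
  if (ok(relaxed)) return(relaxed)
  # strict dialect: names occupy the first 10 characters, sequential layout
  strict <- parse_phylip_strict(nb[-1], nseq, ncol)
  if (ok(strict)) return(strict)
  stop_input("phylip parse failed: content does not match the %d x %d header",
             nseq, ncol)
}

#' @noRd
parse_phylip_strict <- function(body, nseq, ncol) {
  if (length(body) < nseq) return(NULL)
  ids <- character(nseq); rows <- character(nseq)
  for (i in seq_len(nseq)) {
    ln <- body[i]
    if (nchar(ln) <= 10) return(NULL)
    ids[i] <- trimws(substr(ln, 1, 10))
    rows[i] <- gsub("\\s", "", substr(ln, 11, nchar(ln)))
  }
  # interleaved continuation blocks, in sequence order
  extra <- body[-seq_len(nseq)]
  extra <- extra[trimws(extra) != ""]
  if (length(extra)) {
    if (length(extra) %% nseq != 0) return(NULL)
    for (b in seq_len(length(extra) / nseq)) {
      for (i in seq_len(nseq)) {
        rows[i] <- paste0(rows[i], gsub("\\s", "", extra[(b - 1) * nseq + i]))
      }
    }
  }
  list(ids = ids, rows = rows)
}

#' @noRd
parse_stockholm <- function(text) {
  via_biostrings(text, "stockholm", ".sto")
}

# --- fixture/test writers ------------------------------------------------

#' Write an alignment to one of the supported formats
#'
#' Primarily used to build test fixtures and to round-trip alignments; the
#' output of every writer is accepted by [read_alignment()].
#'
#' @param aln A [new_alignment()] object.
#' @param format One of the five supported format tags.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The formatted text, invisibly when written to `path`.
#' @export
write_alignment <- function(aln, format = "fasta", path = NULL) {
  format <- match.arg(format, MSA_FORMATS)
  txt <- switch(format,
    fasta = write_fasta(aln),
    clustal = write_clustal(aln),
    msf = write_msf(aln),
    phylip = write_phylip(aln),
    stockholm = write_stockholm(aln))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @noRd
write_fasta <- function(aln) {
  paste0(paste0(">", aln$ids, "\n", aln$rows, collapse = "\n"), "")
}

#' @noRd
write_clustal <- function(aln) {
  width <- 60
  pad <- max(nchar(aln$ids)) + 4
  blocks <- character(0)
  for (start in seq(1, aln$n_columns, by = width)) {
    seg <- substr(aln$rows, start, min(start + width - 1, aln$n_columns))
    blocks <- c(blocks,
                paste0(formatC(aln$ids, width = -pad), seg, collapse = "\n"))
  }
  paste0("CLUSTAL multiple sequence alignment\n\n",
         paste(blocks, collapse = "\n\n"), "\n")
}

# GCG checksum over the sequence characters, as expected in MSF headers
#' @noRd
gcg_checksum <- function(row) {
  v <- utf8ToInt(row)
  sum(((seq_along(v) - 1) %% 57 + 1) * v) %% 10000
}

#' @noRd
write_msf <- function(aln) {
  type <- if (aln$alphabet == "nucleotide") "N" else "P"
  rows_msf <- gsub("-", ".", aln$rows, fixed = TRUE)
  checks <- vapply(rows_msf, gcg_checksum, numeric(1))
  hdr <- sprintf("  MSF: %d  Type: %s  Check: %d ..",
                 aln$n_columns, type, sum(checks) %% 10000)
  names_blk <- sprintf(" Name: %s oo  Len: %d  Check: %d  Weight: 1.00",
                       aln$ids, aln$n_columns, checks)
  pad <- max(nchar(aln$ids)) + 2
  width <- 50
  blocks <- character(0)
  for (start in seq(1, aln$n_columns, by = width)) {
    seg <- substr(rows_msf, start, min(start + width - 1, aln$n_columns))
    blocks <- c(blocks,
                paste0(formatC(aln$ids, width = -pad), seg, collapse = "\n"))
  }
  paste0("PileUp\n\n", hdr, "\n\n", paste(names_blk, collapse = "\n"),
         "\n\n//\n\n", paste(blocks, collapse = "\n\n"), "\n")
}

#' @noRd
write_phylip <- function(aln) {
  pad <- max(nchar(aln$ids), 10) + 2
  paste0(sprintf(" %d %d\n", length(aln$ids), aln$n_columns),
         paste0(formatC(aln$ids, width = -pad), aln$rows, collapse = "\n"),
         "\n")
}

#' @noRd
write_stockholm <- function(aln) {
  pad <- max(nchar(aln$ids)) + 2
  paste0("# STOCKHOLM 1.0\n",
         paste0(formatC(aln$ids, width = -pad), aln$rows, collapse = "\n"),
         "\n//\n")
}

# --- Newick trees --------------------------------------------------------

#' Read a rooted phylogenetic tree in Newick format
#'
#' @param source A file path or the Newick string itself.
#' @return An [ape::read.tree()] `phylo` object with unique leaf labels.
#' @examples
#' read_newick("(A:1,(B:1,C:1):1);")
#' @export
read_newick <- function(source) {
  text <- source_text(source)
  text <- trimws(text)
  if (!nzchar(text)) stop_input("empty Newick input")
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close)
    stop_input("Newick parse failed: unbalanced parentheses (%d '(' vs %d ')')",
               open, close)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop_input("Newick parse failed: %s",
                                   conditionMessage(e)))
  if (is.null(tree) || is.null(tree$tip.label))
    stop_input("Newick parse failed near character %d", nchar(text))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop_input("duplicate leaf labels in tree: %s", paste(dup, collapse = ", "))
  tree
}

#' Serialize a tree to a Newick string
#' @param tree A `phylo` object.
#' @param path Optional output file.
#' @return The Newick text.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
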