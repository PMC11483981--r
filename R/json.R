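# JSON import/export of graphs and layouts, for debugging and golden-file
# tests. The graph schema is {n_columns, n_sequences, ids, alphabet,
# nodes: [{id, column, symbol, members}], edges: [{src, dst, members}]}
# with 0-based columns and sequence indices.

#' Serialize a POA graph to JSON
#' @param g A `poa_graph`.
#' @param path Optional output file.
#' @return The JSON text (invisibly when written to `path`).
#' @export
poa_to_json <- function(g, path = NULL) {
  obj <- list(
    n_columns = g$n_columns, n_sequences = g$n_sequences,
    ids = g$ids, alphabet = g$alphabet,
    nodes = lapply(seq_len(nrow(g$nodes)), function(i)
      list(id = g$nodes$node_id[i], column = g$nodes$column[i],
           symbol = g$nodes$symbol[i], members = g$nodes$members[[i]])),
    edges = lapply(seq_len(nrow(g$edges)), function(i)
      list(src = g$edges$src[i], dst = g$edges$dst[i],
           members = g$edges$members[[i]])))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Load a POA graph from JSON
#' @param source A file path or JSON text.
#' @return A `poa_graph`.
#' @export
poa_from_json <- function(source) {
  obj <- jsonlite::fromJSON(source_text(source), simplifyVector = FALSE)
  nodes <- data.frame(
    node_id = vapply(obj$nodes, `[[`, character(1), "id"),
    column = vapply(obj$nodes, function(n) as.integer(n$column), integer(1)),
    symbol = vapply(obj$nodes, `[[`, character(1), "symbol"),
    stringsAsFactors = FALSE)
  nodes$members <- lapply(obj$nodes, function(n)
    sort(as.integer(unlist(n$members))))
  edges <- data.frame(
    src = vapply(obj$edges, `[[`, character(1), "src"),
    dst = vapply(obj$edges, `[[`, character(1), "dst"),
    stringsAsFactors = FALSE)
  edges$members <- lapply(obj$edges, function(e)
    sort(as.integer(unlist(e$members))))
  structure(list(n_columns = as.integer(obj$n_columns),
                 n_sequences = as.integer(obj$n_sequences),
                 ids = as.character(unlist(obj$ids)),
                 alphabet = obj$alphabet,
                 nodes = nodes, edges = edges),
            class = "poa_graph")
}

#' Serialize a layout to JSON
#'
#' Captures node placements, link geometry (anchors, thickness, sublinks)
#' and the column x positions, sufficient for golden-file comparisons.
#'
#' @param layout A `poa_layout`.
#' @param path Optional output file.
#' @return The JSON text (invisibly when written to `path`).
#' @export
layout_to_json <- function(layout, path = NULL) {
  pl <- layout$placements
  lk <- layout$links
  obj <- list(
    range = layout$range,
    flow_unit = layout$flow_unit,
    column_x = as.list(layout$column_x),
    placements = lapply(seq_len(nrow(pl)), function(i)
      list(node_id = pl$node_id[i], x = pl$x[i], y = pl$y[i],
           width = pl$width[i], height = pl$height[i])),
    links = lapply(seq_len(nrow(lk)), function(i)
      list(src = lk$src[i], dst = lk$dst[i], shape = lk$shape[i],
           x0 = lk$x0[i], y0 = lk$y0[i], x1 = lk$x1[i], y1 = lk$y1[i],
           thickness = lk$thickness[i], span = lk$span[i],
           sublinks = lapply(seq_len(nrow(lk$sublinks[[i]])), function(j)
             list(selected = lk$sublinks[[i]]$selected[j],
                  offset = lk$sublinks[[i]]$offset[j],
                  thickness = lk$sublinks[[i]]$thickness[j])))))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
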