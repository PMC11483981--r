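# Static SVG output: a Sankey panel, an alignment-matrix panel sharing the
# Sankey's column x-coordinates, and an optional rectangular cladogram
# whose leaf y-centers equal the matrix row y-centers. Everything is
# emitted in a fixed order with fixed number formatting, so identical
# inputs give byte-identical documents. Hover bubbles of the interactive
# original are replaced by embedded <title> descriptions.

# fixed text metrics (units per character at the built-in font size);
# a metrics table rather than OS font queries keeps output deterministic
CHAR_W <- 7.2
ROW_H <- 16
MARGIN <- 20

#' Rendering options
#'
#' @param show_column_separators Draw vertical grid lines between columns.
#' @param show_column_numbers Label columns (1-based) above the Sankey
#'   panel.
#' @param column_label_map Optional named vector mapping 1-based column
#'   numbers (as names) to custom labels.
#' @param panels Subset of `c("sankey", "matrix", "tree")` to draw.
#' @param tooltip Embed a `<title>` description (column, symbol, member
#'   ids) in every node and link.
#' @param matrix_text Draw residue letters inside matrix cells (skipped
#'   automatically when cells are narrower than a character).
#' @return A `render_options` list.
#' @export
render_options <- function(show_column_separators = TRUE,
                           show_column_numbers = TRUE,
                           column_label_map = NULL,
                           panels = c("sankey", "matrix", "tree"),
                           tooltip = TRUE, matrix_text = TRUE) {
  panels <- match.arg(panels, c("sankey", "matrix", "tree"),
                      several.ok = TRUE)
  if (length(panels) == 0) stop_input("at least one panel required")
  structure(list(show_column_separators = show_column_separators,
                 show_column_numbers = show_column_numbers,
                 column_label_map = column_label_map, panels = panels,
                 tooltip = tooltip, matrix_text = matrix_text),
            class = "render_options")
}

#' Render a POA Sankey visualization to SVG
#'
#' @param g A `poa_graph`.
#' @param layout A `poa_layout` computed from `g`.
#' @param aln The alignment the graph was built from (drives the matrix
#'   panel).
#' @param tree Optional `phylo` tree; leaves must match the alignment ids.
#' @param selection Optional `selection_state`; selected flows are filled
#'   with the scheme's highlight color and unselected flows dimmed.
#' @param scheme Optional [color_scheme()]; defaults to a scheme matching
#'   the graph's symbols.
#' @param opts [render_options()].
#' @param grouping Optional `residue_grouping` used to color matrix cells
#'   when the graph was simplified (so matrix and Sankey colors agree).
#' @param consensus Optional node-id vector (a [consensus_path()] result)
#'   whose node/edge chain is drawn in the highlight color.
#' @return The SVG document as a single string.
#' @export
render_svg <- function(g, layout, aln, tree = NULL, selection = NULL,
                       scheme = NULL, opts = render_options(),
                       grouping = NULL, consensus = NULL) {
  if (!all(layout$placements$node_id %in% g$nodes$node_id))
    stop_input("layout does not belong to this graph")
  if (length(aln$ids) != g$n_sequences || !identical(aln$ids, g$ids))
    stop_input("alignment does not match the graph's sequences")
  if (!is.null(tree)) check_tree_alignment(tree, aln)
  if (is.null(scheme)) scheme <- auto_scheme(g)
  if (is.null(selection)) selection <- new_selection(g$n_sequences)
  active <- length(selection$selected) > 0
  layout <- nest_by_selection(layout, selection)
  cfg <- layout$config
  lo <- layout$range[1]; hi <- layout$range[2]

  draw_tree <- !is.null(tree) && "tree" %in% opts$panels
  draw_matrix <- "matrix" %in% opts$panels
  draw_sankey <- "sankey" %in% opts$panels

  tree_w <- if (draw_tree) 130 else 0
  label_w <- if (draw_matrix) max(nchar(aln$ids)) * CHAR_W + 12 else 0
  x_off <- MARGIN + tree_w + label_w
  header_h <- if (opts$show_column_numbers) 18 else 0
  sankey_top <- MARGIN + header_h
  sankey_h <- if (draw_sankey) cfg$canvas_height else 0
  matrix_top <- sankey_top + sankey_h + (if (draw_sankey) 30 else 0)
  n_rows <- length(aln$ids)
  matrix_h <- if (draw_matrix || draw_tree) n_rows * ROW_H else 0
  width <- x_off + cfg$canvas_width + MARGIN
  height <- matrix_top + matrix_h + MARGIN

  row_order <- aln$ids
  tree_frag <- NULL
  if (draw_tree) {
    tree_frag <- render_tree_panel(
      tree, aln, selection, opts,
      x0 = MARGIN, y0 = matrix_top, width = tree_w - 10,
      row_height = ROW_H)
    row_order <- tree_frag$order
  }

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
      "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\" ",
      "font-family=\"monospace\" font-size=\"12\">"),
      fmt_num(width), fmt_num(height), fmt_num(width), fmt_num(height)),
    sprintf("<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"#ffffff\"/>",
            fmt_num(width), fmt_num(height)))

  out <- c(out, render_grid(layout, opts, x_off, sankey_top, sankey_h,
                            matrix_top, matrix_h, cfg))
  if (draw_sankey)
    out <- c(out, render_sankey_panel(g, layout, scheme, opts, active,
                                      x_off, sankey_top, consensus))
  if (draw_matrix)
    out <- c(out, render_matrix_panel(aln, layout, scheme, selection, opts,
                                      grouping, x_off, label_w, matrix_top,
                                      row_order, cfg))
  if (draw_tree) out <- c(out, tree_frag$svg)
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

#' @noRd
render_grid <- function(layout, opts, x_off, sankey_top, sankey_h,
                        matrix_top, matrix_h, cfg) {
  out <- "<g class=\"grid\" stroke=\"#d0d0d0\" stroke-width=\"0.5\">"
  cols <- as.integer(names(layout$column_x))
  xs <- x_off + unname(layout$column_x)
  y_end <- matrix_top + matrix_h
  if (opts$show_column_separators && length(cols) > 1) {
    mids <- utils::head(xs, -1) + diff(xs) / 2 + cfg$node_width / 2
    out <- c(out, sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke-dasharray=\"3 3\"/>",
      vapply(mids, fmt_num, ""), fmt_num(sankey_top),
      vapply(mids, fmt_num, ""), fmt_num(y_end)))
  }
  if (opts$show_column_numbers) {
    step <- max(1L, ceiling(length(cols) / 25))
    lab_cols <- cols[seq(1, length(cols), by = step)]
    lab_x <- xs[seq(1, length(cols), by = step)] + cfg$node_width / 2
    labels <- as.character(lab_cols + 1L)   # rendered labels are 1-based
    if (!is.null(opts$column_label_map)) {
      hit <- labels %in% names(opts$column_label_map)
      labels[hit] <- opts$column_label_map[labels[hit]]
    }
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" text-anchor=\"middle\" fill=\"#555555\" stroke=\"none\">%s</text>",
      vapply(lab_x, fmt_num, ""), fmt_num(sankey_top - 5),
      xml_escape(labels)))
  }
  c(out, "</g>")
}

#' @noRd
render_sankey_panel <- function(g, layout, scheme, opts, active,
                                x_off, y_off, consensus) {
  pl <- layout$placements
  lk <- layout$links
  cons_edges <- character(0)
  cons_nodes <- character(0)
  if (!is.null(consensus) && length(consensus)) {
    cons_nodes <- consensus
    if (length(consensus) > 1)
      cons_edges <- paste(consensus[-length(consensus)], consensus[-1],
                          sep = ">")
  }
  src_sym <- pl$symbol[match(lk$src, pl$node_id)]
  base_col <- scheme_color(scheme, ifelse(is.na(src_sym), "-", src_sym))
  draw <- z_order(lk)

  # expand sublinks into one flat frame, in drawing order, then build all
  # ribbon paths vectorized (formatC vectorizes, so this stays fast on
  # graphs with tens of thousands of links)
  nsub <- vapply(lk$sublinks, nrow, integer(1))[draw]
  li <- rep(draw, nsub)
  offset <- unlist(lapply(lk$sublinks[draw], `[[`, "offset"))
  thick <- unlist(lapply(lk$sublinks[draw], `[[`, "thickness"))
  sel <- unlist(lapply(lk$sublinks[draw], `[[`, "selected"))
  x0 <- lk$x0[li] + x_off; y0 <- lk$y0[li] + offset + y_off
  x1 <- lk$x1[li] + x_off; y1 <- lk$y1[li] + offset + y_off
  mx <- (x0 + x1) / 2
  d <- sprintf(
    "M %s %s C %s %s %s %s %s %s L %s %s C %s %s %s %s %s %s Z",
    fmt_num(x0), fmt_num(y0), fmt_num(mx), fmt_num(y0),
    fmt_num(mx), fmt_num(y1), fmt_num(x1), fmt_num(y1),
    fmt_num(x1), fmt_num(y1 + thick), fmt_num(mx), fmt_num(y1 + thick),
    fmt_num(mx), fmt_num(y0 + thick), fmt_num(x0), fmt_num(y0 + thick))
  on_cons <- paste(lk$src[li], lk$dst[li], sep = ">") %in% cons_edges
  fill <- ifelse(sel | on_cons, scheme$highlight_color, base_col[li])
  opac <- ifelse(active & !sel, scheme$dim_opacity, 0.6)
  title <- if (opts$tooltip) {
    mem_ids <- vapply(lk$members, function(m)
      paste(g$ids[m + 1L], collapse = ", "), character(1))
    sprintf("<title>%s &#8594; %s (%d): %s</title>",
            xml_escape(lk$src[li]), xml_escape(lk$dst[li]),
            lengths(lk$members)[li], xml_escape(mem_ids[li]))
  } else ""
  ribbons <- sprintf(
    "<path d=\"%s\" fill=\"%s\" fill-opacity=\"%s\">%s</path>",
    d, fill, fmt_num(opac), title)

  node_fill <- scheme_color(scheme, pl$symbol)
  ntitle <- if (opts$tooltip) {
    nmem_ids <- vapply(pl$members, function(m)
      paste(g$ids[m + 1L], collapse = ", "), character(1))
    sprintf("<title>column %d, %s (%d): %s</title>",
            pl$column + 1L, xml_escape(pl$symbol), lengths(pl$members),
            xml_escape(nmem_ids))
  } else ""
  stroke <- ifelse(pl$node_id %in% cons_nodes,
                   sprintf(" stroke=\"%s\" stroke-width=\"2\"",
                           scheme$highlight_color),
                   " stroke=\"#333333\" stroke-width=\"0.5\"")
  nodes <- sprintf(
    "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"%s>%s</rect>",
    fmt_num(x_off + pl$x), fmt_num(y_off + pl$y),
    fmt_num(pl$width), fmt_num(pl$height), node_fill, stroke, ntitle)
  c("<g class=\"sankey\">", ribbons, nodes, "</g>")
}

#' @noRd
render_matrix_panel <- function(aln, layout, scheme, selection, opts,
                                grouping, x_off, label_w, y_off,
                                row_order, cfg) {
  m <- alignment_matrix(aln)
  cols <- as.integer(names(layout$column_x))
  xs <- x_off + unname(layout$column_x)
  out <- "<g class=\"matrix\">"
  sel_ids <- aln$ids[selection$selected + 1L]
  show_text <- isTRUE(opts$matrix_text) && cfg$node_width >= CHAR_W
  for (r in seq_along(row_order)) {
    id <- row_order[r]
    yc <- y_off + (r - 0.5) * ROW_H
    lab_fill <- if (id %in% sel_ids) scheme$highlight_color else "#000000"
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" fill=\"%s\" dominant-baseline=\"middle\">%s</text>",
      fmt_num(x_off - label_w + 4), fmt_num(yc), lab_fill, xml_escape(id)))
    syms <- m[id, cols + 1L]
    keys <- if (!is.null(grouping))
      ifelse(syms == "-", "-", group_of(syms, grouping)) else syms
    fills <- scheme_color(scheme, keys)
    fills[syms == "-"] <- "#ffffff"
    cell <- sprintf(
      "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"#e0e0e0\" stroke-width=\"0.3\"/>",
      vapply(xs, fmt_num, ""), fmt_num(y_off + (r - 1) * ROW_H),
      fmt_num(cfg$node_width), fmt_num(ROW_H), fills)
    out <- c(out, cell)
    if (show_text) {
      out <- c(out, sprintf(
        "<text x=\"%s\" y=\"%s\" text-anchor=\"middle\" dominant-baseline=\"middle\" fill=\"#000000\">%s</text>",
        vapply(xs + cfg$node_width / 2, fmt_num, ""), fmt_num(yc),
        xml_escape(syms)))
    }
  }
  c(out, "</g>")
}

#' Render the phylogenetic tree panel
#'
#' Draws a rectangular cladogram (uniform depth steps, branch lengths
#' ignored) whose leaf order also becomes the matrix row order. Children
#' of every internal node are ladderized deterministically: smaller clades
#' first, ties by smallest descendant label. Edges whose entire descendant
#' leaf set is selected are drawn in the highlight color.
#'
#' @param tree A `phylo` tree.
#' @param aln The matching alignment.
#' @param selection A `selection_state` (or `NULL`).
#' @param opts [render_options()].
#' @param x0,y0 Top-left corner of the panel in canvas units.
#' @param width Panel width.
#' @param row_height Vertical space per leaf; leaf y-centers are
#'   `y0 + (i - 0.5) * row_height`.
#' @return List with `svg` (character vector of SVG elements), `order`
#'   (leaf labels top to bottom) and `leaf_y` (named vector of leaf
#'   y-centers).
#' @export
render_tree_panel <- function(tree, aln, selection = NULL,
                              opts = render_options(), x0 = 0, y0 = 0,
                              width = 120, row_height = ROW_H) {
  check_tree_alignment(tree, aln)
  if (is.null(selection)) selection <- new_selection(length(aln$ids))
  sel_ids <- aln$ids[selection$selected + 1L]

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  n_desc <- integer(ntip + tree$Nnode)
  min_lab <- character(ntip + tree$Nnode)
  fill_desc <- function(v) {
    if (v <= ntip) {
      n_desc[v] <<- 1L
      min_lab[v] <<- tree$tip.label[v]
    } else {
      for (k in kids_of[[as.character(v)]]) fill_desc(k)
      ks <- kids_of[[as.character(v)]]
      n_desc[v] <<- sum(n_desc[ks])
      min_lab[v] <<- min(min_lab[ks])
    }
  }
  fill_desc(root)

  order <- character(0)
  depth <- integer(ntip + tree$Nnode)
  dfs <- function(v, d) {
    depth[v] <<- d
    if (v <= ntip) {
      order <<- c(order, tree$tip.label[v])
    } else {
      ks <- kids_of[[as.character(v)]]
      ks <- ks[order(n_desc[ks], min_lab[ks])]
      for (k in ks) dfs(k, d + 1L)
    }
  }
  dfs(root, 0L)

  leaf_y <- stats::setNames(y0 + (seq_along(order) - 0.5) * row_height,
                            order)
  max_d <- max(depth)
  node_x <- x0 + depth / max(max_d, 1) * (width - 4)
  node_y <- numeric(ntip + tree$Nnode)
  node_y[seq_len(ntip)] <- unname(leaf_y[tree$tip.label])
  post_y <- function(v) {
    if (v <= ntip) return(node_y[v])
    ys <- vapply(kids_of[[as.character(v)]], post_y, numeric(1))
    node_y[v] <<- mean(range(ys))
    node_y[v]
  }
  post_y(root)

  leaves_under <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(kids_of[[as.character(v)]], leaves_under))
  }
  hi_col <- default_schemes()$nucleotide$highlight_color
  out <- "<g class=\"tree\" fill=\"none\" stroke-width=\"1\">"
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    lv <- leaves_under(ch)
    hl <- length(lv) > 0 && all(lv %in% sel_ids) && length(sel_ids) > 0
    col <- if (hl) hi_col else "#444444"
    cls <- if (hl) " class=\"highlight\"" else ""
    out <- c(out, sprintf(
      "<path d=\"M %s %s L %s %s L %s %s\" stroke=\"%s\"%s/>",
      fmt_num(node_x[p]), fmt_num(node_y[p]),
      fmt_num(node_x[p]), fmt_num(node_y[ch]),
      fmt_num(node_x[ch]), fmt_num(node_y[ch]), col, cls))
  }
  out <- c(out, "</g>")
  list(svg = out, order = order, leaf_y = leaf_y)
}

#' Wrap an SVG document in a single static HTML page
#' @param svg_text The SVG document text.
#' @param title Page title.
#' @return A self-contained HTML document string embedding the SVG
#'   unchanged.
#' @export
render_html <- function(svg_text, title = "POA Sankey view") {
  body <- sub("^<\\?xml[^>]*\\?>\n", "", svg_text)
  paste0("<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
         "<title>", xml_escape(title), "</title>\n</head>\n<body>\n",
         body, "\n</body>\n</html>\n")
}
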