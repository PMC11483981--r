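# Deterministic Sankey geometry. Columns of the displayed range are placed
# left to right at uniform spacing; node heights and link thicknesses are
# member counts times a single flow unit, so the drawing conserves flow
# exactly. Vertical node order inside a column comes from a two-pass
# barycenter sweep seeded by descending member count.

#' Layout configuration
#'
#' @param canvas_width,canvas_height Drawing area in abstract canvas units
#'   (origin top-left, y grows downward, as in SVG).
#' @param node_width Width of every node rectangle, units.
#' @param min_node_gap Minimum vertical gap between nodes of one column.
#' @param column_range Inclusive 0-based `c(lo, hi)` pair of columns to
#'   display; `NULL` means the whole graph.
#' @param flow_unit Canvas height allotted per member sequence; `NULL`
#'   auto-scales so the fullest column exactly fits `canvas_height`.
#' @param y_overrides Optional named numeric vector: node id -> vertical
#'   offset (units, positive = down) added after automatic placement.
#' @return A `layout_config` list.
#' @export
layout_config <- function(canvas_width = 1000, canvas_height = 600,
                          node_width = 12, min_node_gap = 6,
                          column_range = NULL, flow_unit = NULL,
                          y_overrides = NULL) {
  if (canvas_width <= 0 || canvas_height <= 0)
    stop_input("canvas dimensions must be positive")
  if (node_width <= 0) stop_input("node_width must be positive")
  if (min_node_gap < 0) stop_input("min_node_gap must be non-negative")
  structure(list(canvas_width = canvas_width, canvas_height = canvas_height,
                 node_width = node_width, min_node_gap = min_node_gap,
                 column_range = column_range, flow_unit = flow_unit,
                 y_overrides = y_overrides),
            class = "layout_config")
}

# stack nodes of one column top to bottom in the given order, vertically
# centering the block on the canvas
#' @noRd
stack_column <- function(heights, gap, canvas_height) {
  k <- length(heights)
  block <- sum(heights) + gap * (k - 1)
  y0 <- (canvas_height - block) / 2
  tops <- y0 + cumsum(c(0, utils::head(heights, -1) + gap))
  tops
}

#' Compute the Sankey layout of a POA graph
#'
#' @param g A `poa_graph`.
#' @param cfg A [layout_config()].
#' @return A `poa_layout`: `placements` data frame (`node_id`, `column`,
#'   `x`, `y`, `width`, `height`, `count`), `links` data frame (anchors,
#'   thickness, span, shape, `sublinks` list-column), `column_x` (named by
#'   0-based column), `flow_unit`, `range`, and the config. Edges with one
#'   endpoint outside the displayed range are clipped to boundary stubs;
#'   edges entirely outside are dropped.
#' @export
compute_layout <- function(g, cfg = layout_config()) {
  rng <- cfg$column_range
  if (is.null(rng)) rng <- c(0L, g$n_columns - 1L)
  rng <- as.integer(rng)
  if (length(rng) != 2 || anyNA(rng) || rng[1] > rng[2] ||
      rng[1] < 0 || rng[2] >= g$n_columns)
    stop_input("column range %s:%s outside graph with %d columns",
               rng[1], rng[2], g$n_columns)
  lo <- rng[1]; hi <- rng[2]

  keep <- g$nodes$column >= lo & g$nodes$column <= hi
  nd <- g$nodes[keep, , drop = FALSE]
  if (nrow(nd) == 0) stop_input("no nodes in column range %d:%d", lo, hi)
  nd$count <- lengths(nd$members)

  cols <- lo:hi
  ncolr <- length(cols)
  # spacing is quantized to 1/1024 canvas units so that column x-gaps are
  # exactly uniform in floating point, not merely within rounding error
  spacing <- if (ncolr == 1) 0 else
    floor((cfg$canvas_width - cfg$node_width) / (ncolr - 1) * 1024) / 1024
  column_x <- if (ncolr == 1) {
    stats::setNames((cfg$canvas_width - cfg$node_width) / 2, cols)
  } else {
    stats::setNames((cols - lo) * spacing, cols)
  }

  # flow unit: tallest column exactly fits the canvas
  u <- cfg$flow_unit
  if (is.null(u)) {
    per_col <- split(seq_len(nrow(nd)), nd$column)
    u <- Inf
    for (ix in per_col) {
      avail <- cfg$canvas_height - cfg$min_node_gap * (length(ix) - 1)
      if (avail <= 0)
        stop_input("canvas_height too small for %d nodes in one column",
                   length(ix))
      u <- min(u, avail / sum(nd$count[ix]))
    }
    # dyadic quantization (multiples of 1/1024) keeps every derived
    # height/thickness sum exact in floating point
    if (u >= 1 / 1024) u <- floor(u * 1024) / 1024
  }
  if (!is.finite(u) || u <= 0) stop_input("invalid flow unit")

  nd$height <- nd$count * u
  nd$x <- unname(column_x[as.character(nd$column)])
  nd$width <- cfg$node_width

  # initial vertical order: descending member count, ties by symbol
  per_col <- split(seq_len(nrow(nd)), nd$column)
  order_in <- lapply(per_col, function(ix)
    ix[order(-nd$count[ix], nd$symbol[ix])])
  nd$y <- NA_real_
  restack <- function(order_in) {
    for (ix in order_in) {
      nd$y[ix] <<- stack_column(nd$height[ix], cfg$min_node_gap,
                                cfg$canvas_height)
    }
  }
  restack(order_in)

  # adjacency over in-range edges for the barycenter passes
  ed <- g$edges
  esrc_i <- match(ed$src, nd$node_id)
  edst_i <- match(ed$dst, nd$node_id)
  internal <- !is.na(esrc_i) & !is.na(edst_i)
  nlev <- factor(seq_len(nrow(nd)), levels = seq_len(nrow(nd)))
  pred_of <- split(esrc_i[internal],
                   factor(edst_i[internal], levels = levels(nlev)))
  succ_of <- split(edst_i[internal],
                   factor(esrc_i[internal], levels = levels(nlev)))

  center <- function(i) nd$y[i] + nd$height[i] / 2
  sweep_pass <- function(order_in, neighbors, col_seq) {
    for (c in col_seq) {
      ix <- order_in[[as.character(c)]]
      if (is.null(ix) || length(ix) < 2) next
      key <- vapply(ix, function(i) {
        nb <- neighbors[[i]]
        if (is.null(nb) || length(nb) == 0) center(i)
        else mean(center(nb))
      }, numeric(1))
      ix <- ix[order(key)]          # stable: ties keep current order
      order_in[[as.character(c)]] <- ix
      nd$y[ix] <<- stack_column(nd$height[ix], cfg$min_node_gap,
                                cfg$canvas_height)
    }
    order_in
  }
  if (ncolr > 1) {
    order_in <- sweep_pass(order_in, pred_of, as.character((lo + 1):hi))
    order_in <- sweep_pass(order_in, succ_of, as.character(rev(lo:(hi - 1))))
  }

  # manual vertical adjustments come last
  if (!is.null(cfg$y_overrides) && length(cfg$y_overrides)) {
    ov <- cfg$y_overrides
    j <- match(names(ov), nd$node_id)
    nd$y[j[!is.na(j)]] <- nd$y[j[!is.na(j)]] + unname(ov[!is.na(j)])
  }

  placements <- nd[, c("node_id", "column", "symbol", "x", "y",
                       "width", "height", "count")]
  rownames(placements) <- NULL
  placements$members <- nd$members

  links <- build_links(g, nd, esrc_i, edst_i, lo, hi, u, cfg)
  band_bottom <- max(nd$y + nd$height)

  structure(list(placements = placements, links = links,
                 column_x = column_x, flow_unit = u,
                 range = c(lo, hi), band_bottom = band_bottom,
                 config = cfg),
            class = "poa_layout")
}

# anchor computation: at every node, attached link thicknesses tile the
# node side top to bottom, links sorted by the opposite endpoint's center
#' @noRd
build_links <- function(g, nd, esrc_i, edst_i, lo, hi, u, cfg) {
  ed <- g$edges
  scol <- node_column(ed$src)
  dcol <- node_column(ed$dst)
  shape <- rep(NA_character_, nrow(ed))
  shape[!is.na(esrc_i) & !is.na(edst_i)] <- "forward"
  shape[!is.na(esrc_i) & is.na(edst_i) & dcol > hi] <- "stub_right"
  shape[is.na(esrc_i) & !is.na(edst_i) & scol < lo] <- "stub_left"
  keep <- which(!is.na(shape))
  if (length(keep) == 0) {
    links <- data.frame(src = character(0), dst = character(0),
                        shape = character(0), span = integer(0),
                        x0 = numeric(0), y0 = numeric(0),
                        x1 = numeric(0), y1 = numeric(0),
                        thickness = numeric(0), stringsAsFactors = FALSE)
    links$members <- list()
    links$sublinks <- list()
    return(links)
  }
  lk <- data.frame(src = ed$src[keep], dst = ed$dst[keep],
                   shape = shape[keep], span = dcol[keep] - scol[keep],
                   stringsAsFactors = FALSE)
  lk$members <- ed$members[keep]
  lk$thickness <- lengths(lk$members) * u
  lk$src_i <- esrc_i[keep]
  lk$dst_i <- edst_i[keep]
  lk$x0 <- lk$y0 <- lk$x1 <- lk$y1 <- NA_real_

  ctr <- nd$y + nd$height / 2
  # source-side tiling (right side of src node)
  by_src <- split(seq_len(nrow(lk)), lk$src_i)
  for (nm in names(by_src)) {
    i <- as.integer(nm)
    li <- by_src[[nm]]
    opp <- ifelse(is.na(lk$dst_i[li]), Inf, ctr[lk$dst_i[li]])
    li <- li[order(opp, lk$dst[li])]
    off <- cumsum(c(0, utils::head(lk$thickness[li], -1)))
    lk$x0[li] <- nd$x[i] + nd$width[i]
    lk$y0[li] <- nd$y[i] + off
  }
  # target-side tiling (left side of dst node)
  by_dst <- split(seq_len(nrow(lk)), lk$dst_i)
  for (nm in names(by_dst)) {
    i <- as.integer(nm)
    li <- by_dst[[nm]]
    opp <- ifelse(is.na(lk$src_i[li]), -Inf, ctr[lk$src_i[li]])
    li <- li[order(opp, lk$src[li])]
    off <- cumsum(c(0, utils::head(lk$thickness[li], -1)))
    lk$x1[li] <- nd$x[i]
    lk$y1[li] <- nd$y[i] + off
  }
  # boundary stubs: clipped ends run horizontally to the range edge
  sr <- lk$shape == "stub_right"
  lk$x1[sr] <- cfg$canvas_width
  lk$y1[sr] <- lk$y0[sr]
  sl <- lk$shape == "stub_left"
  lk$x0[sl] <- 0
  lk$y0[sl] <- lk$y1[sl]

  lk$src_i <- lk$dst_i <- NULL
  # default nesting: one sublink spanning the whole flow
  lk$sublinks <- lapply(seq_len(nrow(lk)), function(i) {
    s <- data.frame(selected = FALSE, offset = 0,
                    thickness = lk$thickness[i])
    s$members <- lk$members[i]
    s
  })
  rownames(lk) <- NULL
  lk
}

#' Drawing order of links
#'
#' Longest column span draws first (underneath), then thicker before
#' thinner; the sort is stable so equal links keep input order.
#'
#' @param links The `links` data frame of a `poa_layout` (or any frame
#'   with `span` and `thickness` columns).
#' @return An integer permutation giving the drawing order.
#' @export
z_order <- function(links) {
  order(-links$span, -links$thickness)
}

#' Decompose link flows by a selection
#'
#' Every link is split into at most two stacked sublinks: the selected
#' members first, then the unselected remainder, with thicknesses
#' proportional to their counts. Empty strips are omitted; thicknesses
#' always sum exactly to the parent link's.
#'
#' @param layout A `poa_layout`.
#' @param selection A `selection_state`.
#' @return The layout with updated `sublinks`.
#' @export
nest_by_selection <- function(layout, selection) {
  u <- layout$flow_unit
  layout$links$sublinks <- lapply(seq_len(nrow(layout$links)), function(i) {
    m <- layout$links$members[[i]]
    a <- m[m %in% selection$selected]
    b <- m[!m %in% selection$selected]
    parts <- list()
    if (length(a)) parts[[length(parts) + 1]] <-
      list(selected = TRUE, members = a)
    if (length(b)) parts[[length(parts) + 1]] <-
      list(selected = FALSE, members = b)
    off <- 0
    s <- data.frame(selected = vapply(parts, `[[`, logical(1), "selected"),
                    offset = NA_real_,
                    thickness = vapply(parts, function(p)
                      length(p$members) * u, numeric(1)))
    s$offset <- cumsum(c(0, utils::head(s$thickness, -1)))
    s$members <- lapply(parts, `[[`, "members")
    s
  })
  layout
}

#' @export
print.poa_layout <- function(x, ...) {
  cat(sprintf(
    "<poa_layout> columns %d:%d, %d nodes, %d links, flow unit %.3f\n",
    x$range[1], x$range[2], nrow(x$placements), nrow(x$links), x$flow_unit))
  invisible(x)
}
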