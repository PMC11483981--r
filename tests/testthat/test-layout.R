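# Sankey geometry: proportional heights, uniform spacing, link tiling,
# ribbon shapes, z-order and selection nesting.

test_that("a single node sits at the column x, vertically centered", {
  g <- build_poa(new_alignment("one", "A"))
  lay <- compute_layout(g, layout_config(canvas_width = 100,
                                         canvas_height = 50))
  pl <- lay$placements
  expect_identical(nrow(pl), 1L)
  expect_equal(pl$x, unname(lay$column_x["0"]))
  expect_equal(pl$y + pl$height / 2, 25)
})

test_that("node heights are proportional to member counts", {
  a <- new_alignment(paste0("s", 1:6),
                     c("AT", "AT", "AT", "AT", "CT", "CT"))
  lay <- compute_layout(build_poa(a))
  pl <- lay$placements
  hA <- pl$height[pl$node_id == "0/A"]
  hC <- pl$height[pl$node_id == "0/C"]
  expect_equal(hA / hC, 2, tolerance = 1e-6)
  for (seed in 1:5) {
    lay <- compute_layout(build_poa(random_fixture(seed, max_seqs = 12,
                                                   max_cols = 30)))
    pl <- lay$placements
    expect_true(all(abs(pl$height / pl$count - lay$flow_unit) <
                      1e-6 * lay$flow_unit), info = seed)
  }
})

test_that("columns are spaced exactly uniformly", {
  for (seed in 1:5) {
    lay <- compute_layout(build_poa(random_fixture(seed, max_cols = 80)))
    gaps <- diff(unname(lay$column_x))
    expect_identical(max(gaps) - min(gaps), 0)
  }
})

test_that("no rectangle overlap and exact link tiling on random layouts", {
  for (seed in 1:15) {
    g <- build_poa(random_fixture(seed, max_seqs = 15, max_cols = 40))
    lay <- compute_layout(g)
    expect_identical(check_layout_geometry(g, lay), "ok", info = seed)
  }
})

test_that("column range views clip out-of-range edges to boundary stubs", {
  a <- new_alignment(c("a", "b", "c"), c("A-CGT", "ABCGT", "AB-GT"))
  g <- build_poa(a)
  lay <- compute_layout(g, layout_config(column_range = c(1, 3)))
  expect_identical(sort(unique(lay$placements$column)), 1:3)
  shapes <- table(lay$links$shape)
  expect_gt(shapes[["stub_left"]], 0)   # edges entering from column 0
  expect_gt(shapes[["stub_right"]], 0)  # edges leaving to column 4
  sl <- lay$links[lay$links$shape == "stub_left", ]
  expect_true(all(sl$x0 == 0))
  sr <- lay$links[lay$links$shape == "stub_right", ]
  expect_true(all(sr$x1 == lay$config$canvas_width))
  expect_error(compute_layout(g, layout_config(column_range = c(3, 9))),
               class = "poaflow_input_error")
})

test_that("identical inputs give bit-identical layouts", {
  g <- build_poa(random_fixture(3))
  cfg <- layout_config(column_range = c(0, 20))
  expect_identical(compute_layout(g, cfg), compute_layout(g, cfg))
})

test_that("y overrides shift single nodes after automatic placement", {
  g <- build_poa(new_alignment(c("a", "b"), c("AC", "AG")))
  base <- compute_layout(g)
  moved <- compute_layout(g, layout_config(
    y_overrides = c("1/C" = 25)))
  d <- moved$placements$y - base$placements$y
  expect_equal(d[moved$placements$node_id == "1/C"], 25)
  expect_equal(d[moved$placements$node_id != "1/C"], c(0, 0))
})

test_that("forward ribbons hit their anchors; long links cross each
           intermediate column once", {
  g <- build_poa(new_alignment(c("a", "b"), c("A--T", "ACGT")))
  lay <- compute_layout(g)
  lk <- lay$links
  long <- lk[lk$span == 3, ]
  expect_identical(nrow(long), 1L)
  p <- link_path(as.list(long[1, c("shape", "x0", "y0", "x1", "y1",
                                   "thickness")]), n = 101)
  expect_equal(p$top[1, ], c(x = long$x0, y = long$y0))
  expect_equal(p$top[101, ], c(x = long$x1, y = long$y1))
  for (cc in c("1", "2")) {
    cx <- unname(lay$column_x[cc])
    for (curve in list(p$top, p$bottom)) {
      crossings <- sum(diff(sign(curve[, "x"] - cx)) != 0)
      expect_identical(crossings, 1L, info = cc)
    }
  }
})

test_that("feedback arcs route below the occupied band", {
  link <- list(shape = "feedback", x0 = 300, y0 = 200, x1 = 100, y1 = 200,
               thickness = 8)
  p <- link_path(link, clearance = 30, n = 200)
  expect_true(all(p$top[, "y"] >= 200 - 1e-9))
  expect_true(all(p$bottom[, "y"] >= 200 - 1e-9))
})

test_that("reversing joins loop off the shared side", {
  left <- link_path(list(shape = "reverse_left", x0 = 100, y0 = 50,
                         x1 = 100, y1 = 150, thickness = 5), n = 100)
  expect_true(min(left$top[, "x"]) < 100)
  expect_true(all(left$top[c(1, 100), "x"] == 100))
  right <- link_path(list(shape = "reverse_right", x0 = 100, y0 = 50,
                          x1 = 100, y1 = 150, thickness = 5), n = 100)
  expect_true(max(right$top[, "x"]) > 100)
})

test_that("z-order draws long spans first, then thick, stably", {
  links <- data.frame(span = c(1, 3, 2), thickness = c(5, 1, 9))
  expect_identical(z_order(links), c(2L, 3L, 1L))
  ties <- data.frame(span = c(2, 2, 2), thickness = c(2, 5, 5))
  expect_identical(z_order(ties), c(2L, 3L, 1L))  # 5s keep input order
})

test_that("selection nesting conserves thickness exactly", {
  g <- build_poa(generate_msa_fixture(10, 25, "nucleotide", 0.3, 0.2,
                                      seed = 31))
  lay <- compute_layout(g)
  # empty selection: one sublink identical to the parent
  empty <- nest_by_selection(lay, new_selection(10))
  for (s in empty$links$sublinks) {
    expect_identical(nrow(s), 1L)
    expect_false(s$selected)
  }
  expect_equal(vapply(empty$links$sublinks, function(s) s$thickness,
                      numeric(1)),
               empty$links$thickness)
  # full selection: one sublink, flagged selected
  full <- nest_by_selection(lay, local({
    st <- new_selection(10); st$selected <- 0:9; st
  }))
  expect_true(all(vapply(full$links$sublinks, function(s)
    nrow(s) == 1 && s$selected, logical(1))))
  # random selections: sums are exact, selected strip stacks first
  for (seed in 1:10) {
    set.seed(seed)
    st <- new_selection(10)
    st$selected <- sort(sample(0:9, sample(1:9, 1)))
    nested <- nest_by_selection(lay, st)
    for (i in seq_len(nrow(nested$links))) {
      s <- nested$links$sublinks[[i]]
      expect_identical(sum(s$thickness), nested$links$thickness[i])
      expect_identical(s$offset,
                       cumsum(c(0, utils::head(s$thickness, -1))))
      if (nrow(s) == 2) expect_true(s$selected[1] && !s$selected[2])
    }
  }
})
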