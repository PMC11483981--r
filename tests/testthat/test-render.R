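# SVG output: well-formedness, determinism, panel synchronization,
# color totality, tree panel ordering and highlighting.

render_fixture <- function(seed = 41, n = 6, L = 18) {
  aln <- generate_msa_fixture(n, L, "nucleotide", 0.3, 0.15, seed = seed)
  g <- build_poa(aln)
  list(aln = aln, g = g, lay = compute_layout(g),
       tree = generate_tree_fixture(aln$ids, seed = seed + 1))
}

svg_xml <- function(txt) xml2::read_xml(charToRaw(paste0(txt, "\n")))

test_that("the sankey group holds exactly one primitive per node and link", {
  aln <- new_alignment(c("a", "b"), c("AC", "AG"))
  g <- build_poa(aln)
  svg <- render_svg(g, compute_layout(g), aln)
  doc <- svg_xml(svg)
  sankey <- xml2::xml_find_first(doc, "//*[@class='sankey']")
  rects <- xml2::xml_find_all(sankey, ".//*[local-name()='rect']")
  paths <- xml2::xml_find_all(sankey, ".//*[local-name()='path']")
  expect_identical(length(rects), nrow(g$nodes))
  expect_identical(length(paths), nrow(g$edges))
})

test_that("rendering is byte-deterministic and yields well-formed XML", {
  fx <- render_fixture()
  sel <- parse_selection(c("seq:s1", "seq:s3"), fx$g)
  one <- render_svg(fx$g, fx$lay, fx$aln, tree = fx$tree, selection = sel)
  two <- render_svg(fx$g, fx$lay, fx$aln, tree = fx$tree, selection = sel)
  expect_identical(one, two)
  expect_s3_class(svg_xml(one), "xml_document")
  doc <- svg_xml(one)
  expect_identical(xml2::xml_name(doc), "svg")
  expect_identical(xml2::xml_attr(doc, "version"), "1.1")
})

test_that("matrix cells share the sankey column x-coordinates exactly", {
  for (seed in c(43, 44, 45)) {
    fx <- render_fixture(seed)
    doc <- svg_xml(render_svg(fx$g, fx$lay, fx$aln))
    sankey_x <- sort(unique(as.numeric(xml2::xml_attr(
      xml2::xml_find_all(doc, "//*[@class='sankey']/*[local-name()='rect']"),
      "x"))))
    matrix_x <- sort(unique(as.numeric(xml2::xml_attr(
      xml2::xml_find_all(doc, "//*[@class='matrix']/*[local-name()='rect']"),
      "x"))))
    expect_identical(matrix_x, sankey_x, info = seed)
  }
})

test_that("tree leaves and matrix rows share y-centers; order is ladderized", {
  aln <- new_alignment(c("A", "B", "C"), c("GAT", "GCT", "GGT"))
  tr <- read_newick("(A,(B,C));")
  panel <- render_tree_panel(tr, aln, y0 = 100, row_height = 16)
  expect_identical(panel$order, c("A", "B", "C"))
  expect_equal(unname(panel$leaf_y), 100 + (1:3 - 0.5) * 16)
  # bigger random tree: leaf y-centers follow the returned order exactly
  fx <- render_fixture(47, n = 9)
  p2 <- render_tree_panel(fx$tree, fx$aln, y0 = 0, row_height = 16)
  expect_setequal(p2$order, fx$aln$ids)
  expect_equal(unname(p2$leaf_y[p2$order]),
               (seq_along(p2$order) - 0.5) * 16)
})

test_that("exactly the selected subtree edges carry the highlight color", {
  aln <- new_alignment(c("A", "B", "C"), c("GAT", "GCT", "GGT"))
  tr <- read_newick("(A,(B,C));")
  st <- new_selection(3)
  st$selected <- 1:2   # B and C
  panel <- render_tree_panel(tr, aln, selection = st)
  hl <- grepl("class=\"highlight\"", panel$svg)
  expect_identical(sum(hl), 3L)  # stem of the cherry + its two leaf edges
  none <- render_tree_panel(tr, aln, selection = new_selection(3))
  expect_false(any(grepl("class=\"highlight\"", none$svg)))
})

test_that("built-in schemes are total with fallbacks, never erroring", {
  sch <- default_schemes()
  expect_true(all(c("A", "C", "G", "T", "U", "N", "-") %in%
                    names(sch$nucleotide$mapping)))
  expect_true(all(c("electrically charged", "polar uncharged",
                    "hydrophobic", "special", "other") %in%
                    names(sch$group$mapping)))
  expect_identical(scheme_color(sch$protein, "J"), sch$protein$fallback)
  expect_identical(scheme_color(sch$nucleotide, c("A", "??")),
                   c(unname(sch$nucleotide$mapping["A"]),
                     sch$nucleotide$fallback))
})

test_that("selection dims unselected flows and highlights selected ones", {
  fx <- render_fixture(49)
  sel <- parse_selection("seq:s1", fx$g)
  svg <- render_svg(fx$g, fx$lay, fx$aln, selection = sel)
  sch <- default_schemes()$nucleotide
  expect_true(grepl(sch$highlight_color, svg, fixed = TRUE))
  expect_true(grepl(sprintf("fill-opacity=\"%s\"",
                            sub("0\\.", ".", "0.35")), svg) ||
                grepl("fill-opacity=\"0.35\"", svg, fixed = TRUE))
})

test_that("tooltips embed member descriptions; consensus chain is marked", {
  fx <- render_fixture(53, n = 4, L = 8)
  cons <- consensus_path(fx$g)$path
  svg <- render_svg(fx$g, fx$lay, fx$aln, consensus = cons)
  expect_true(grepl("<title>column 1,", svg, fixed = TRUE))
  expect_identical(
    lengths(regmatches(svg, gregexpr("stroke-width=\"2\"", svg))),
    length(cons))
  off <- render_svg(fx$g, fx$lay, fx$aln,
                    opts = render_options(tooltip = FALSE))
  expect_false(grepl("<title>", off, fixed = TRUE))
})

test_that("render options control separators, numbers and panels", {
  fx <- render_fixture(59)
  bare <- render_svg(fx$g, fx$lay, fx$aln,
                     opts = render_options(show_column_separators = FALSE,
                                           show_column_numbers = FALSE,
                                           panels = "sankey"))
  expect_false(grepl("stroke-dasharray", bare, fixed = TRUE))
  expect_false(grepl("class=\"matrix\"", bare, fixed = TRUE))
  named <- render_svg(fx$g, fx$lay, fx$aln, opts = render_options(
    column_label_map = c("1" = "start")))
  expect_true(grepl(">start<", named, fixed = TRUE))
  expect_error(render_options(panels = character(0)))
})

test_that("html wrapper embeds the svg unchanged", {
  fx <- render_fixture(61, n = 3, L = 6)
  svg <- render_svg(fx$g, fx$lay, fx$aln)
  html <- render_html(svg)
  expect_true(startsWith(html, "<!DOCTYPE html>"))
  expect_true(grepl(sub("^<\\?xml[^>]*\\?>\n", "", svg), html,
                    fixed = TRUE))
})

test_that("mismatched inputs are rejected", {
  fx <- render_fixture(63)
  other <- build_poa(generate_msa_fixture(6, 18, "nucleotide", 0.5, 0.1,
                                          seed = 99))
  expect_error(render_svg(other, fx$lay, fx$aln),
               class = "poaflow_input_error")
  bad_tree <- generate_tree_fixture(c("x1", "x2", "x3"), seed = 2)
  expect_error(render_svg(fx$g, fx$lay, fx$aln, tree = bad_tree),
               class = "poaflow_input_error")
})
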