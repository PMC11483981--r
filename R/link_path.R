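# Ribbon geometry for a single link. Forward ribbons (and boundary stubs)
# are cubic-curve bands from the right side of the source to the left side
# of the target; the engine additionally supports feedback arcs routed
# below the occupied canvas band and reversing joins looping off one side.
# POA graphs are DAGs and only ever emit forward shapes; the other shapes
# exist at the engine level for cyclic/bidirected inputs.

#' @noRd
bezier_points <- function(p0, c1, c2, p1, n = 33) {
  t <- seq(0, 1, length.out = n)
  bx <- function(a, b, c, d)
    (1 - t)^3 * a + 3 * (1 - t)^2 * t * b + 3 * (1 - t) * t^2 * c + t^3 * d
  cbind(x = bx(p0[1], c1[1], c2[1], p1[1]),
        y = bx(p0[2], c1[2], c2[2], p1[2]))
}

#' Drawable curve specification of a link
#'
#' @param link A single row of a layout's `links` frame (as a list or
#'   one-row data frame) with fields `shape`, `x0`, `y0`, `x1`, `y1` and
#'   `thickness`. Anchor y-coordinates are the top of the ribbon for
#'   forward shapes; feedback arcs interpret them as the node bottoms they
#'   depart from.
#' @param clearance Extra routing distance for feedback/reversing shapes,
#'   canvas units.
#' @param n Samples per boundary curve (used for geometry checks).
#' @return List with `d` (an SVG path string for the closed ribbon
#'   outline), `top` and `bottom` (n-by-2 sampled point matrices of the two
#'   boundary curves).
#' @export
link_path <- function(link, clearance = 20, n = 33) {
  sh <- link$shape
  x0 <- link$x0; y0 <- link$y0; x1 <- link$x1; y1 <- link$y1
  th <- link$thickness
  if (sh %in% c("forward", "stub_right", "stub_left")) {
    mx <- (x0 + x1) / 2
    top <- bezier_points(c(x0, y0), c(mx, y0), c(mx, y1), c(x1, y1), n)
    bottom <- bezier_points(c(x0, y0 + th), c(mx, y0 + th),
                            c(mx, y1 + th), c(x1, y1 + th), n)
    d <- sprintf(
      "M %s %s C %s %s %s %s %s %s L %s %s C %s %s %s %s %s %s Z",
      fmt_num(x0), fmt_num(y0), fmt_num(mx), fmt_num(y0),
      fmt_num(mx), fmt_num(y1), fmt_num(x1), fmt_num(y1),
      fmt_num(x1), fmt_num(y1 + th), fmt_num(mx), fmt_num(y1 + th),
      fmt_num(mx), fmt_num(y0 + th), fmt_num(x0), fmt_num(y0 + th))
  } else if (sh == "feedback") {
    # target lies left of source; route below the occupied band
    ry <- max(y0, y1) + clearance
    top <- bezier_points(c(x0, y0), c(x0, ry), c(x1, ry), c(x1, y1), n)
    ry2 <- ry + th
    bottom <- bezier_points(c(x0, y0), c(x0, ry2), c(x1, ry2), c(x1, y1), n)
    d <- sprintf(
      "M %s %s C %s %s %s %s %s %s C %s %s %s %s %s %s Z",
      fmt_num(x0), fmt_num(y0), fmt_num(x0), fmt_num(ry),
      fmt_num(x1), fmt_num(ry), fmt_num(x1), fmt_num(y1),
      fmt_num(x1), fmt_num(ry2), fmt_num(x0), fmt_num(ry2),
      fmt_num(x0), fmt_num(y0))
  } else if (sh %in% c("reverse_left", "reverse_right")) {
    sgn <- if (sh == "reverse_left") -1 else 1
    bx <- max(abs(y1 - y0) / 2, clearance)
    c1 <- c(x0 + sgn * bx, y0)
    c2 <- c(x1 + sgn * bx, y1)
    top <- bezier_points(c(x0, y0), c1, c2, c(x1, y1), n)
    bottom <- bezier_points(c(x0, y0 + th),
                            c(x0 + sgn * (bx + th), y0 + th),
                            c(x1 + sgn * (bx + th), y1 + th),
                            c(x1, y1 + th), n)
    d <- sprintf(
      "M %s %s C %s %s %s %s %s %s L %s %s C %s %s %s %s %s %s Z",
      fmt_num(x0), fmt_num(y0), fmt_num(c1[1]), fmt_num(c1[2]),
      fmt_num(c2[1]), fmt_num(c2[2]), fmt_num(x1), fmt_num(y1),
      fmt_num(x1), fmt_num(y1 + th),
      fmt_num(x1 + sgn * (bx + th)), fmt_num(y1 + th),
      fmt_num(x0 + sgn * (bx + th)), fmt_num(y0 + th),
      fmt_num(x0), fmt_num(y0 + th))
  } else {
    stop_internal("unknown link shape: %s", sh)
  }
  list(d = d, top = top, bottom = bottom)
}
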