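# Built-in color schemes. The same scheme colors both the Sankey nodes and
# the matrix cells, so the two panels read identically.

#' Construct a color scheme
#'
#' @param mapping Named character vector: symbol or group label -> color.
#' @param name Scheme identifier.
#' @param highlight_color Color used for selected flows/labels/subtrees.
#' @param dim_opacity Opacity applied to unselected flows while a
#'   selection is active (fraction in `[0, 1]`).
#' @param fallback Color for symbols absent from `mapping`; guarantees the
#'   scheme is total over any alphabet.
#' @return A `color_scheme` object.
#' @export
color_scheme <- function(mapping, name = "custom",
                         highlight_color = "#e6194b", dim_opacity = 0.35,
                         fallback = "#b0b0b0") {
  if (dim_opacity < 0 || dim_opacity > 1)
    stop_input("dim_opacity must lie in [0, 1]")
  structure(list(mapping = mapping, name = name,
                 highlight_color = highlight_color,
                 dim_opacity = dim_opacity, fallback = fallback),
            class = "color_scheme")
}

#' Resolve symbols to colors
#' @param scheme A [color_scheme()].
#' @param symbols Character vector of symbols or group labels.
#' @return Character vector of colors; unknown symbols get the scheme's
#'   fallback, never an error.
#' @export
scheme_color <- function(scheme, symbols) {
  out <- unname(scheme$mapping[symbols])
  out[is.na(out)] <- scheme$fallback
  out
}

#' Built-in color schemes
#'
#' Three palettes: a 4+N nucleotide scheme, a Clustal-like per-residue
#' protein scheme, and one color per default physicochemical group. All
#' are plain named vectors and can be overridden from a config file.
#'
#' @return List with elements `nucleotide`, `protein` and `group`, each a
#'   [color_scheme()].
#' @export
default_schemes <- function() {
  nuc <- c(A = "#4caf50", C = "#2196f3", G = "#ff9800", T = "#f44336",
           U = "#f44336", N = "#9e9e9e", "-" = "#ffffff")
  prot <- c(A = "#80a0f0", I = "#80a0f0", L = "#80a0f0", M = "#80a0f0",
            F = "#80a0f0", W = "#80a0f0", V = "#80a0f0",
            K = "#f01505", R = "#f01505",
            E = "#c048c0", D = "#c048c0",
            N = "#15c015", Q = "#15c015", S = "#15c015", T = "#15c015",
            C = "#f08080", G = "#f09048", P = "#c0c000",
            H = "#15a4a4", Y = "#15a4a4", "-" = "#ffffff")
  grp <- c("electrically charged" = "#d62728",
           "polar uncharged" = "#2ca02c",
           "hydrophobic" = "#1f77b4",
           "special" = "#ff7f0e",
           "other" = "#9e9e9e", "-" = "#ffffff")
  list(nucleotide = color_scheme(nuc, "nucleotide-default"),
       protein = color_scheme(prot, "protein-clustal-like"),
       group = color_scheme(grp, "group-default"))
}

# pick the scheme matching a graph: group labels -> group scheme,
# otherwise by alphabet
#' @noRd
auto_scheme <- function(g) {
  sch <- default_schemes()
  if (all(g$nodes$symbol %in% names(sch$group$mapping))) return(sch$group)
  if (g$alphabet == "nucleotide") sch$nucleotide else sch$protein
}
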