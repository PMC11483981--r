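# Internal helpers shared across modules.

#' Signal an input/validation error
#'
#' Errors of class `poaflow_input_error` map to exit code 2 at the CLI
#' boundary; everything else is an internal error (exit 1).
#' @noRd
stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poaflow_input_error", "poaflow_error")))
}

#' @noRd
stop_internal <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = "poaflow_error"))
}

#' Format a number for SVG output
#'
#' Fixed-precision, trailing zeros trimmed, so identical doubles always
#' serialize to identical text (byte determinism).
#' @noRd
fmt_num <- function(x) {
  s <- formatC(x, format = "f", digits = 3)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Escape text for inclusion in XML attribute/content
#' @noRd
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Run code with a temporarily seeded RNG, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# read a "source" argument that may be a file path or literal text
# (text is recognized by embedded newlines or a leading format signature)
#' @noRd
source_text <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
}
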