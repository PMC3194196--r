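#' Canonicalize text dialects before mention recognition
#'
#' Published variant descriptions mix several substitution-arrow dialects
#' (right-arrow glyphs, \code{"-->"}, \code{"=>"}, spaced dash-arrows) and
#' several dash characters (en dash, em dash, minus sign). Recognition runs
#' on a canonical form in which every arrow dialect is a single \code{">"}
#' and every dash is an ASCII hyphen; the returned offset map carries every
#' canonical character back to its position in the original document so
#' match spans can be reported on the original text.
#'
#' The transformation is idempotent and the identity on text containing no
#' dialect characters.
#'
#' @param text a single character string (UTF-8).
#' @return a list with \code{text} (canonical string) and \code{map}
#'   (integer vector, one entry per canonical character, holding the
#'   1-based character offset in the original text; for a collapsed arrow
#'   the offset of its final \code{">"} or arrow glyph).
#' @examples
#' canonicalizeText("894G-->T")$text  # "894G>T"
#' @export
canonicalizeText <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  n <- length(chars)
  if (n == 0L) return(list(text = "", map = integer()))
  # pass 1: per-character substitutions (1:1, map is identity)
  dash  <- chars %in% c("\u2013", "\u2014", "\u2212")
  arrow <- chars %in% c("\u2192", "\u21d2")
  chars[dash]  <- "-"
  chars[arrow] <- ">"
  s1 <- paste(chars, collapse = "")
  # pass 2: collapse multi-character arrows ("-->", "- ->", "=>", ...) to ">"
  m <- gregexpr("[-=](?: ?[-=])* ?>", s1, perl = TRUE)[[1]]
  keep <- rep(TRUE, n)
  if (m[1] != -1L) {
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      span <- seq.int(m[i], m[i] + len[i] - 1L)
      keep[span[-length(span)]] <- FALSE  # keep only the final ">"
    }
  }
  list(text = paste(chars[keep], collapse = ""), map = which(keep))
}
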