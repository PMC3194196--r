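#' Construct a position expression
#'
#' @param scheme one of \code{"LEGACY1993"}, \code{"GENOMIC"},
#'   \code{"IVS"}, \code{"HGVS_C"}.
#' @param anchor signed integer anchor (\code{NA} for intronic IVS forms).
#' @param offset signed intronic offset, 0 for exonic positions.
#' @param ivs_index intron ordinal (IVS intronic forms).
#' @param star whether the anchor is a 3'UTR asterisk number (HGVS only).
#' @param region region label; inferred heuristically when missing (the
#'   definitive region always comes from rendering against a gene model).
#' @return a \linkS4class{PositionExpression}.
#' @examples
#' positionExpression("HGVS_C", anchor = 26, offset = 2)  # c.26+2
#' @export
positionExpression <- function(scheme, anchor = NA, offset = 0L,
                               ivs_index = NA, star = FALSE,
                               region = NULL) {
  anchor <- as.integer(anchor); offset <- as.integer(offset)
  ivs_index <- as.integer(ivs_index)
  if (is.null(region)) {
    region <- if (scheme == "GENOMIC") "GENOMIC"
      else if (offset != 0L) "INTRON"
      else if (star) "THREE_UTR"
      else if (!is.na(anchor) && anchor < 0L) "FIVE_UTR"
      else "CDS"
  }
  new("PositionExpression", scheme = scheme, region = region,
      anchor = anchor, offset = offset, ivs_index = ivs_index, star = star)
}

setMethod("show", "PositionExpression", function(object) {
  cat(sprintf("PositionExpression [%s] %s (%s)\n", object@scheme,
              formatPosition(object), object@region))
})

#' Parse a textual position expression under a given scheme
#'
#' Accepts the textual forms of each convention: bare and signed integers
#' (\code{"894"}, \code{"-225"}), two-number intronic forms
#' (\code{"252+2"}), IVS forms (\code{"IVS2+2"}) and HGVS asterisk forms
#' (\code{"*46"}, \code{"*46-2"}). A leading \code{"c."} or \code{"g."}
#' prefix is tolerated and stripped. Position zero does not exist in any
#' transcript-based convention and is rejected.
#'
#' @param text the position expression string.
#' @param scheme the convention to parse under.
#' @return a \linkS4class{PositionExpression}.
#' @examples
#' parsePosition("26+2", "HGVS_C")
#' parsePosition("IVS2+2", "IVS")
#' @export
parsePosition <- function(text, scheme) {
  stopifnot(scheme %in% POSITION_SCHEMES)
  text <- sub("^[cg]\\.", "", trimws(text))
  m <- regexec("^IVS([0-9]+)([+-][0-9]+)$", text)[[1]]
  if (m[1] != -1L) {
    if (scheme != "IVS")
      stop("IVS intronic forms belong to the IVS scheme: ", text)
    g <- regmatches(text, list(m))[[1]]
    off <- as.integer(g[3])
    if (off == 0L) stop("intronic offset zero is not defined: ", text)
    return(positionExpression("IVS", anchor = NA, offset = off,
                              ivs_index = as.integer(g[2])))
  }
  m <- regexec("^(\\*)?(-?[0-9]+)([+-][0-9]+)?$", text)[[1]]
  if (m[1] == -1L) stop("malformed position expression: ", text)
  g <- regmatches(text, list(m))[[1]]
  star <- g[2] == "*"
  anchor <- as.integer(g[3])
  offset <- if (nzchar(g[4])) as.integer(g[4]) else 0L
  if (star && scheme != "HGVS_C")
    stop("asterisk positions belong to the HGVS scheme: ", text)
  if (anchor == 0L && scheme != "GENOMIC")
    stop("position zero is not defined in scheme ", scheme)
  if (scheme == "GENOMIC" && (offset != 0L || anchor < 1L))
    stop("genomic positions are positive absolute integers: ", text)
  positionExpression(scheme, anchor = anchor, offset = offset, star = star)
}

#' Format a position expression as text
#'
#' @param expr a \linkS4class{PositionExpression}.
#' @param prefix include the scheme prefix (\code{"c."} for HGVS,
#'   \code{"g."} for genomic).
#' @return a character string, e.g. \code{"252+2"}, \code{"IVS2+2"},
#'   \code{"c.-225"}.
#' @export
formatPosition <- function(expr, prefix = TRUE) {
  base <- switch(expr@scheme,
    GENOMIC = paste0(if (prefix) "g." else "", expr@anchor),
    LEGACY1993 = if (expr@offset == 0L) as.character(expr@anchor)
      else sprintf("%d%+d", expr@anchor, expr@offset),
    IVS = if (!is.na(expr@ivs_index))
        sprintf("IVS%d%+d", expr@ivs_index, expr@offset)
      else as.character(expr@anchor),
    HGVS_C = {
      a <- paste0(if (expr@star) "*" else "", expr@anchor)
      s <- if (expr@offset == 0L) a else sprintf("%s%+d", a, expr@offset)
      paste0(if (prefix) "c." else "", s)
    })
  base
}

# identity key for deduplication of representations
positionKey <- function(expr) {
  paste(expr@scheme, expr@anchor, expr@offset, expr@ivs_index, expr@star,
        sep = "|")
}
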