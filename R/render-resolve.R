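exonRegionOf <- function(geo, tpos) {
  if (tpos < geo$t_atg) "FIVE_UTR"
  else if (tpos <= geo$t_stop) "CDS"
  else "THREE_UTR"
}

#' Render a reference position under a nomenclature convention
#'
#' Converts an absolute 1-based reference position into the coordinate
#' expression a given convention would print for it:
#' \describe{
#'   \item{LEGACY1993}{transcript numbering from the 5' cap site (+1 at
#'     the cap, upstream -1, -2, ..., no zero); intronic positions are
#'     written as the transcript coordinate of the nearer exon edge plus a
#'     signed distance.}
#'   \item{GENOMIC}{the absolute 1-based position on the stated reference
#'     sequence, unchanged.}
#'   \item{IVS}{exonic positions numbered from the A of the start codon
#'     (+1 at the A, upstream negative, no zero); intronic positions as
#'     \code{IVSn+d} / \code{IVSn-d} with the intron ordinal and the
#'     signed distance to the nearer exon boundary.}
#'   \item{HGVS_C}{coding positions 1..n, 5'UTR negative, 3'UTR asterisk
#'     numbers counted from the first base after the stop codon; intronic
#'     positions anchored at the nearest exonic coding/UTR coordinate with
#'     a signed distance.}
#' }
#' A position equidistant from both flanking exon boundaries anchors to
#' the 5' (upstream) exon with a \code{+} offset. Positions downstream of
#' the transcript 3' end cannot be expressed in the transcript-based
#' conventions and raise an error.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param gpos 1-based reference position.
#' @param scheme one of \code{"LEGACY1993"}, \code{"GENOMIC"},
#'   \code{"IVS"}, \code{"HGVS_C"}.
#' @return a \linkS4class{PositionExpression}.
#' @examples
#' fx <- mecp2Fixture()
#' formatPosition(renderPosition(fx$model, 10490, "LEGACY1993"))  # "252+2"
#' formatPosition(renderPosition(fx$model, 10490, "HGVS_C"))      # "c.26+2"
#' @export
renderPosition <- function(model, gpos, scheme) {
  stopifnot(is(model, "GeneModel"), scheme %in% POSITION_SCHEMES)
  gpos <- as.integer(gpos)
  if (is.na(gpos) || gpos < 1L)
    stop("reference position out of range: ", gpos)
  if (scheme == "GENOMIC")
    return(positionExpression("GENOMIC", anchor = gpos, region = "GENOMIC"))
  geo <- modelGeometry(model)
  loc <- locateU(geo, geo$toU(gpos))
  if (loc$where == "downstream")
    stop("position ", gpos, " lies downstream of the transcript and has ",
         "no ", scheme, " representation")
  if (scheme == "LEGACY1993") {
    if (loc$where == "upstream")
      return(positionExpression("LEGACY1993", anchor = -loc$dist,
                                region = "UPSTREAM"))
    if (loc$where == "exon")
      return(positionExpression("LEGACY1993", anchor = loc$tpos,
                                region = exonRegionOf(geo, loc$tpos)))
    i <- loc$intron
    if (loc$d5 <= loc$d3)
      positionExpression("LEGACY1993", anchor = geo$cum[i] + geo$w[i],
                         offset = loc$d5, region = "INTRON")
    else
      positionExpression("LEGACY1993", anchor = geo$cum[i + 1L] + 1L,
                         offset = -loc$d3, region = "INTRON")
  } else if (scheme == "IVS") {
    ivsNum <- function(tpos)
      if (tpos >= geo$t_atg) tpos - geo$t_atg + 1L else tpos - geo$t_atg
    if (loc$where == "upstream")
      return(positionExpression("IVS", anchor = ivsNum(1L - loc$dist),
                                region = "UPSTREAM"))
    if (loc$where == "exon")
      return(positionExpression("IVS", anchor = ivsNum(loc$tpos),
                                region = exonRegionOf(geo, loc$tpos)))
    off <- if (loc$d5 <= loc$d3) loc$d5 else -loc$d3
    positionExpression("IVS", anchor = NA, offset = off,
                       ivs_index = loc$intron, region = "INTRON")
  } else {  # HGVS_C
    cAnchor <- function(tpos) {
      if (tpos < geo$t_atg)
        list(anchor = tpos - geo$t_atg, star = FALSE,
             region = "FIVE_UTR")
      else if (tpos <= geo$t_stop)
        list(anchor = tpos - geo$t_atg + 1L, star = FALSE, region = "CDS")
      else
        list(anchor = tpos - geo$t_stop, star = TRUE, region = "THREE_UTR")
    }
    if (loc$where == "upstream")
      return(positionExpression("HGVS_C",
                                anchor = -(geo$t_atg - 1L + loc$dist),
                                region = "UPSTREAM"))
    if (loc$where == "exon") {
      a <- cAnchor(loc$tpos)
      return(positionExpression("HGVS_C", anchor = a$anchor, star = a$star,
                                region = a$region))
    }
    i <- loc$intron
    if (loc$d5 <= loc$d3) {
      a <- cAnchor(geo$cum[i] + geo$w[i])
      positionExpression("HGVS_C", anchor = a$anchor, star = a$star,
                         offset = loc$d5, region = "INTRON")
    } else {
      a <- cAnchor(geo$cum[i + 1L] + 1L)
      positionExpression("HGVS_C", anchor = a$anchor, star = a$star,
                         offset = -loc$d3, region = "INTRON")
    }
  }
}

#' Resolve a position expression to reference positions
#'
#' Inverse of \code{\link{renderPosition}}. Returns a single position for
#' exonic, upstream and genomic expressions. Intronic two-number forms are
#' resolved from the exon edge their anchor denotes: a positive offset
#' counts into the intron from an exon 3' end, a negative offset counts
#' back from an exon 5' start; every consistent reading is returned (the
#' historic conventions allowed describing an intronic base from either
#' flanking exon). An anchor of zero is rejected at parse time; an anchor
#' that does not lie on the transcript (or, for intronic forms, is not an
#' exon-edge coordinate) is unresolvable and raises an error.
#'
#' @param model a \linkS4class{GeneModel}.
#' @param expr a \linkS4class{PositionExpression}, or a string parsed with
#'   \code{\link{parsePosition}} (then \code{scheme} must be given).
#' @param scheme scheme to parse \code{expr} under when it is a string.
#' @return integer vector of 1-based reference positions.
#' @examples
#' fx <- mecp2Fixture()
#' resolvePosition(fx$model, "26+2", "HGVS_C")  # 10490
#' resolvePosition(fx$model, "2", "LEGACY1993") # 4943
#' @export
resolvePosition <- function(model, expr, scheme = NULL) {
  if (is.character(expr)) {
    stopifnot(!is.null(scheme))
    expr <- parsePosition(expr, scheme)
  }
  stopifnot(is(model, "GeneModel"), is(expr, "PositionExpression"))
  if (expr@scheme == "GENOMIC")
    return(as.integer(expr@anchor))
  geo <- modelGeometry(model)

  # map an expression anchor to a transcript position (possibly virtual,
  # i.e. < 1 for upstream continuations)
  anchorTpos <- switch(expr@scheme,
    LEGACY1993 = expr@anchor,
    IVS = if (is.na(expr@anchor)) NA_integer_
      else if (expr@anchor > 0L) geo$t_atg + expr@anchor - 1L
      else geo$t_atg + expr@anchor,
    HGVS_C = if (is.na(expr@anchor)) NA_integer_
      else if (expr@star) geo$t_stop + expr@anchor
      else if (expr@anchor > 0L) geo$t_atg + expr@anchor - 1L
      else geo$t_atg + expr@anchor)

  if (expr@scheme == "IVS" && !is.na(expr@ivs_index)) {
    i <- expr@ivs_index
    if (i < 1L || i >= geo$n_exon)
      stop("intron ordinal ", i, " does not exist in this model")
    u <- if (expr@offset > 0L) geo$ue[i] + expr@offset
         else geo$us[i + 1L] + expr@offset
    if (u <= geo$ue[i] || u >= geo$us[i + 1L])
      stop("IVS offset falls outside intron ", i)
    return(as.integer(geo$fromU(u)))
  }

  if (is.na(anchorTpos)) stop("unresolvable anchor")

  if (expr@offset == 0L) {
    if (anchorTpos >= 1L && anchorTpos <= geo$transcript_length)
      return(as.integer(geo$fromU(geo$uOfTpos(anchorTpos))))
    if (anchorTpos < 1L) {  # upstream continuation of the numbering
      # LEGACY1993 skips zero at the cap (-1 is the base before +1); the
      # ATG-based schemes skip zero at the start codon, which the
      # anchorTpos formula already absorbed
      u <- if (expr@scheme == "LEGACY1993") geo$us[1L] + anchorTpos
           else geo$us[1L] + anchorTpos - 1L
      return(as.integer(geo$fromU(u)))
    }
    stop("anchor beyond the transcript 3' end is unresolvable")
  }

  # intronic two-number form: anchor must denote an exon edge
  hits <- integer()
  exonEndT <- geo$cum + geo$w      # tpos of each exon 3' end
  exonStartT <- geo$cum + 1L       # tpos of each exon 5' start
  if (expr@offset > 0L) {
    i <- which(exonEndT == anchorTpos)
    if (length(i) && i < geo$n_exon) {
      u <- geo$ue[i] + expr@offset
      if (u < geo$us[i + 1L]) hits <- c(hits, geo$fromU(u))
    }
  } else {
    i <- which(exonStartT == anchorTpos)
    if (length(i) && i > 1L) {
      u <- geo$us[i] + expr@offset
      if (u > geo$ue[i - 1L]) hits <- c(hits, geo$fromU(u))
    }
  }
  if (!length(hits))
    stop("intronic anchor ", formatPosition(expr),
         " is not an exon-edge coordinate of this model")
  as.integer(unique(hits))
}

#' Enumerate all nomenclature representations of a position
#'
#' Renders a reference position under every convention for every supplied
#' gene model (several transcripts per gene are tried) and returns the
#' distinct expressions. Every element resolves back to the input position
#' under at least one of the models; conventions that cannot express the
#' position on a given model (e.g. downstream of the transcript) are
#' skipped silently.
#'
#' @param models a \linkS4class{GeneModel} or list of them.
#' @param gpos 1-based reference position.
#' @return list of distinct \linkS4class{PositionExpression} objects
#'   (empty when no model covers the position).
#' @examples
#' fx <- mecp2Fixture()
#' sapply(enumerateRepresentations(fx$model, 10490), formatPosition)
#' @export
enumerateRepresentations <- function(models, gpos) {
  if (is(models, "GeneModel")) models <- list(models)
  out <- list(); seen <- character()
  for (m in models) {
    for (sch in POSITION_SCHEMES) {
      expr <- tryCatch(renderPosition(m, gpos, sch),
                       error = function(e) NULL)
      if (is.null(expr)) next
      key <- positionKey(expr)
      if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1L]] <- expr }
    }
  }
  out
}
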