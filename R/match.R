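mentionAlleles <- function(mention) {
  mu <- strsplit(as.character(mention$mutated), ",", fixed = TRUE)[[1]]
  unique(c(as.character(mention$wild), mu))
}

# which schemes a mention's surface dialect may be interpreted under:
# explicit prefixes pin the scheme; IVS forms pin IVS; unprefixed signed,
# two-number or asterisk forms may be any transcript-based convention;
# bare integers may additionally be genomic
mentionSchemes <- function(mention) {
  hint <- as.character(mention$scheme_hint)
  pt <- as.character(mention$position_text)
  if (identical(hint, "c.")) return("HGVS_C")
  if (identical(hint, "g.")) return("GENOMIC")
  if (identical(hint, "r.")) return(character())  # RNA scheme: parse only
  if (grepl("^IVS", pt)) return("IVS")
  if (grepl("^[1-9][0-9]*$", pt))
    return(c("LEGACY1993", "IVS", "HGVS_C", "GENOMIC"))
  c("LEGACY1993", "IVS", "HGVS_C")
}

#' Validate a nucleotide-level mention against a record
#'
#' The mention's position expression is interpreted under every
#' nomenclature convention compatible with its surface (a
#' \code{c.}-prefixed mention only under HGVS coding numbering, an IVS
#' form only under the IVS convention, unprefixed signed or two-number
#' forms under any transcript-based convention, bare integers additionally
#' as genomic) and resolved against every supplied gene model; the
#' position validates when any reading yields the record's reference
#' position. Alleles validate when the mention's allele set is a subset of
#' the record's alleles, complementing the record's stored alleles first
#' when its orientation is opposite to the linked gene. Wild/mutated order
#' is ignored. Both checks must pass.
#'
#' @param mention one mention row (from \code{\link{findMentions}}).
#' @param record a \linkS4class{SnpRecord}.
#' @param models list of \linkS4class{GeneModel} for the record's genes
#'   (all transcripts are tried).
#' @return a \linkS4class{MatchResult}.
#' @export
matchNsm <- function(mention, record, models) {
  if (is(models, "GeneModel")) models <- list(models)
  models <- Filter(function(m) m@gene_id %in% record@gene_ids, models)
  schemes <- mentionSchemes(mention)
  if (!length(schemes)) return(new("MatchResult"))

  posHit <- NULL
  for (sch in schemes) {
    expr <- tryCatch(parsePosition(as.character(mention$position_text), sch),
                     error = function(e) NULL)
    if (is.null(expr)) next
    if (sch == "GENOMIC") {
      if (record@position == expr@anchor) {
        posHit <- list(scheme = sch, transcript = NA_character_)
        break
      }
      next
    }
    for (m in models) {
      hits <- tryCatch(resolvePosition(m, expr), error = function(e) integer())
      if (record@position %in% hits) {
        posHit <- list(scheme = sch, transcript = m@gene_id)
        break
      }
    }
    if (!is.null(posHit)) break
  }
  if (is.null(posHit)) return(new("MatchResult"))

  flip <- record@orientation == "opposite"
  recAlleles <- if (flip) complementAlleles(record@alleles) else
    record@alleles
  mAll <- mentionAlleles(mention)
  if (!all(mAll %in% NUCLEOTIDES) || !all(mAll %in% recAlleles))
    return(new("MatchResult"))
  new("MatchResult", matched = TRUE, rs_id = record@rs_id,
      scheme = posHit$scheme, strand_flipped = flip,
      direction_flipped = FALSE, transcript = posHit$transcript)
}

#' Validate a protein-level mention against a record
#'
#' Delegates to \code{\link{reconcilePsm}}: the mention's residue position
#' must equal the record's precursor residue position either directly or
#' after a documented maturation offset (initiator-methionine cleavage,
#' N-terminal feature removal), and the residue pair must agree as an
#' unordered set. Records without residue information never match
#' protein-level mentions.
#'
#' @param mention one mention row (from \code{\link{findMentions}}).
#' @param record a \linkS4class{SnpRecord} carrying residue information.
#' @param ann a \linkS4class{ProteinAnnotation} for the record's protein.
#' @return a \linkS4class{MatchResult}.
#' @export
matchPsm <- function(mention, record, ann = proteinAnnotation()) {
  if (is.na(record@residue_position) || !length(record@residues))
    return(new("MatchResult"))
  mpos <- suppressWarnings(as.integer(as.character(mention$position_text)))
  if (is.na(mpos)) return(new("MatchResult"))
  res <- reconcilePsm(mpos, mentionAlleles(mention),
                      record@residue_position, record@residues, ann)
  if (res@matched) res@rs_id <- record@rs_id
  res
}
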