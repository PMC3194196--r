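#' Construct a protein annotation
#'
#' @param protein_id protein accession.
#' @param gene_id linked gene identifier.
#' @param initiator_met_cleaved whether the initiator methionine is
#'   cleaved post-translationally.
#' @param features data.frame with columns \code{kind} (\code{Signal},
#'   \code{Transit}, \code{Peptide}, \code{Propeptide}, \code{Var_seq}),
#'   \code{begin}, \code{end} in precursor residue coordinates.
#' @return a \linkS4class{ProteinAnnotation}.
#' @examples
#' proteinAnnotation("P01374", "LTA", features = data.frame(
#'   kind = "Signal", begin = 1L, end = 34L))
#' @export
proteinAnnotation <- function(protein_id = NA_character_,
                              gene_id = NA_character_,
                              initiator_met_cleaved = FALSE,
                              features = NULL) {
  if (is.null(features))
    features <- data.frame(kind = character(), begin = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  features$begin <- as.integer(features$begin)
  features$end <- as.integer(features$end)
  new("ProteinAnnotation", protein_id = as.character(protein_id),
      gene_id = as.character(gene_id),
      initiator_met_cleaved = isTRUE(initiator_met_cleaved),
      features = features)
}

setMethod("show", "ProteinAnnotation", function(object) {
  cat(sprintf("ProteinAnnotation %s (gene %s) init_met_cleaved=%s\n",
              object@protein_id, object@gene_id,
              object@initiator_met_cleaved))
  f <- object@features
  if (nrow(f))
    cat(paste(sprintf("  %s: %d-%d", f$kind, f$begin, f$end),
              collapse = "\n"), "\n")
})

#' Candidate offsets explaining mature-vs-precursor residue numbering
#'
#' Residue positions in text may be counted on the mature protein while
#' database records count on the precursor. Two mechanisms generate a
#' constant offset: cleavage of the initiator methionine (+1) and removal
#' of an N-terminal maturation segment (Signal, Transit, Peptide or
#' Propeptide feature starting at residue 1; offset = feature length).
#' \code{Var_seq} features are isoform markers and generate no offset.
#' The zero offset is always the first candidate, so the weakest
#' assumption is tried first.
#'
#' @param ann a \linkS4class{ProteinAnnotation}.
#' @return data.frame with columns \code{delta}, \code{provenance}
#'   (\code{NONE}/\code{INIT_MET}/\code{FEATURE}) and \code{feature}
#'   (label of the generating feature, \code{""} otherwise), ordered
#'   NONE, then INIT_MET, then features by position.
#' @examples
#' ann <- proteinAnnotation(features = data.frame(kind = "Signal",
#'                                                begin = 1L, end = 34L))
#' offsetCandidates(ann)$delta  # 0 34
#' @export
offsetCandidates <- function(ann) {
  out <- data.frame(delta = 0L, provenance = "NONE", feature = "",
                    stringsAsFactors = FALSE)
  if (ann@initiator_met_cleaved)
    out <- rbind(out, data.frame(delta = 1L, provenance = "INIT_MET",
                                 feature = ""))
  f <- ann@features
  f <- f[f$begin == 1L & f$kind != "Var_seq", , drop = FALSE]
  if (nrow(f)) {
    f <- f[order(f$begin, f$end), , drop = FALSE]
    out <- rbind(out, data.frame(
      delta = f$end - f$begin + 1L, provenance = "FEATURE",
      feature = sprintf("%s:%d-%d", f$kind, f$begin, f$end)))
  }
  out
}

#' Reconcile a protein-level mention with a record's residue position
#'
#' Succeeds when some candidate offset d satisfies
#' \code{mention_position + d == record_position} and the mention's residue
#' pair equals the record's residue pair as unordered sets (matching is
#' agnostic to which residue is called wild type). Offsets are tried in
#' candidate order (zero first), so the reported explanation is the
#' weakest sufficient one. Unexplained constant offsets (no supporting
#' feature) yield a no-match result, not an error.
#'
#' @param mention_position residue position as written in text.
#' @param mention_residues character vector of one-letter residues (wild
#'   and mutated, any order).
#' @param record_position precursor-coordinate residue position of the
#'   record.
#' @param record_residues the record's residue set.
#' @param ann a \linkS4class{ProteinAnnotation} (may be empty).
#' @return a \linkS4class{MatchResult}; when matched, its
#'   \code{offset_provenance}/\code{offset_delta}/\code{offset_feature}
#'   slots record the explanation used.
#' @examples
#' ann <- proteinAnnotation(initiator_met_cleaved = TRUE)
#' reconcilePsm(34, c("V", "L"), 35, c("V", "L"), ann)
#' @export
reconcilePsm <- function(mention_position, mention_residues,
                         record_position, record_residues,
                         ann = proteinAnnotation()) {
  mention_position <- as.integer(mention_position)
  record_position <- as.integer(record_position)
  if (is.na(mention_position) || is.na(record_position))
    return(new("MatchResult"))
  residuesOk <- setequal(mention_residues, record_residues)
  if (!residuesOk) return(new("MatchResult"))
  cand <- offsetCandidates(ann)
  hit <- which(mention_position + cand$delta == record_position)
  if (!length(hit)) return(new("MatchResult"))
  i <- hit[1L]
  flipped <- length(mention_residues) == 2L &&
    length(record_residues) == 2L &&
    !identical(as.character(mention_residues),
               as.character(record_residues))
  new("MatchResult", matched = TRUE, rs_id = NA_real_,
      offset_provenance = cand$provenance[i],
      offset_delta = cand$delta[i], offset_feature = cand$feature[i],
      direction_flipped = flipped)
}
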