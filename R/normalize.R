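#' Candidate records for a gene set
#'
#' Candidate retrieval mirrors how a normalizer pools its search space: a
#' mention is tentatively associated with every gene mentioned in the
#' document, and every record linked to any of those genes is a candidate.
#' Validation against position and alleles disambiguates afterwards.
#'
#' @param gene_ids character vector of gene identifiers (may be empty).
#' @param store a \linkS4class{SnpStore}.
#' @return list of \linkS4class{SnpRecord}, ordered by rs id.
#' @export
candidateRecords <- function(gene_ids, store) {
  if (!length(gene_ids)) return(list())
  hit <- Filter(function(r) any(r@gene_ids %in% gene_ids), store@records)
  hit[order(vapply(hit, function(r) r@rs_id, numeric(1)))]
}

matchExplanation <- function(res) {
  bits <- character()
  if (!is.na(res@scheme)) bits <- c(bits, paste0("scheme=", res@scheme))
  if (!is.na(res@offset_provenance) && res@offset_provenance != "NONE")
    bits <- c(bits, paste0("offset=", res@offset_provenance))
  if (res@strand_flipped) bits <- c(bits, "strand=flip")
  if (res@direction_flipped) bits <- c(bits, "direction=flip")
  paste(bits, collapse = ";")
}

#' Normalize one mention against a record store
#'
#' Implements the per-mention matching procedure: rs-identifier mentions
#' ground directly to their record; protein-level, nucleotide-level and
#' ambiguous mentions are validated against every candidate record of the
#' supplied genes, pursuing both the protein and the nucleotide path for
#' ambiguous mentions. The outcome status summarises the distinct matching
#' rs ids: \code{UNIQUE} (exactly one), \code{AMBIGUOUS_DUPLICATE}
#' (several, all at the identical reference position — unmerged duplicate
#' records), \code{MULTIPLE_GENES} (several on different genes or
#' positions), \code{NO_MATCH}, or \code{RS_DIRECT}.
#'
#' @param mention one mention row (from \code{\link{findMentions}}).
#' @param gene_ids genes mentioned in the document (perfect gene
#'   recognition is assumed; gene identification is an input).
#' @param store a \linkS4class{SnpStore}.
#' @return a list with \code{status}, \code{rs_ids} (numeric vector of
#'   distinct matching ids), \code{matches} (list of
#'   \linkS4class{MatchResult}) and \code{explanation} (string).
#' @export
normalizeMention <- function(mention, gene_ids, store) {
  out <- function(status, rs_ids = numeric(), matches = list())
    list(status = status, rs_ids = rs_ids, matches = matches,
         explanation = if (length(matches))
           matchExplanation(matches[[1L]]) else "")
  if (identical(as.character(mention$kind), "RS")) {
    rec <- recordByRsId(store, mention$rs_number)
    if (is.null(rec)) return(out("NO_MATCH"))
    m <- new("MatchResult", matched = TRUE, rs_id = rec@rs_id)
    return(out("RS_DIRECT", rec@rs_id, list(m)))
  }
  level <- classifyLevel(mention)
  cands <- candidateRecords(gene_ids, store)
  matches <- list()
  for (rec in cands) {
    if (level %in% c("PSM", "BOTH")) {
      ann <- annotationForGenes(store, rec@gene_ids)
      r <- matchPsm(mention, rec, ann)
      if (r@matched) matches[[length(matches) + 1L]] <- r
    }
    if (level %in% c("NSM", "BOTH")) {
      r <- matchNsm(mention, rec, modelsForGenes(store, rec@gene_ids))
      if (r@matched) matches[[length(matches) + 1L]] <- r
    }
  }
  if (!length(matches)) return(out("NO_MATCH"))
  ids <- unique(vapply(matches, function(m) m@rs_id, numeric(1)))
  if (length(ids) == 1L) return(out("UNIQUE", ids, matches))
  recs <- lapply(ids, function(i) recordByRsId(store, i))
  pos <- vapply(recs, function(r) r@position, integer(1))
  if (length(unique(pos)) == 1L)
    return(out("AMBIGUOUS_DUPLICATE", ids, matches))
  out("MULTIPLE_GENES", ids, matches)
}

#' Check a cited rs identifier against co-mentioned variant descriptions
#'
#' Authors sometimes cite a digit-permuted rs number. When a document
#' contains both an rs mention and a textual variant description, the
#' description can be validated against the cited record: if it does not
#' validate there but does validate against some other candidate record of
#' the document's genes, the citation is flagged inconsistent and the
#' validating ids are suggested as corrections.
#'
#' @param rs_mention the rs mention row.
#' @param variant_mentions mention rows of co-mentioned variant
#'   descriptions (PSM/NSM/ambiguous).
#' @param gene_ids genes mentioned in the document.
#' @param store a \linkS4class{SnpStore}.
#' @return list with \code{status} (\code{"consistent"},
#'   \code{"inconsistent"}, \code{"unknown"} if the cited id is absent
#'   from the store, or \code{"unsupported"} if no candidate validates any
#'   co-mentioned description) and \code{suggested_rs_ids}.
#' @export
checkRsConsistency <- function(rs_mention, variant_mentions, gene_ids,
                               store) {
  res <- function(status, sugg = numeric())
    list(status = status, suggested_rs_ids = sugg)
  cited <- recordByRsId(store, rs_mention$rs_number)
  if (is.null(cited)) return(res("unknown"))
  if (is.null(variant_mentions) || nrow(variant_mentions) == 0L)
    return(res("unsupported"))
  validates <- function(mention, rec) {
    level <- classifyLevel(mention)
    if (level %in% c("PSM", "BOTH")) {
      ann <- annotationForGenes(store, rec@gene_ids)
      if (matchPsm(mention, rec, ann)@matched) return(TRUE)
    }
    if (level %in% c("NSM", "BOTH")) {
      if (matchNsm(mention, rec,
                   modelsForGenes(store, rec@gene_ids))@matched)
        return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(nrow(variant_mentions)))
    if (validates(variant_mentions[i, ], cited)) return(res("consistent"))
  sugg <- numeric()
  for (rec in candidateRecords(gene_ids, store)) {
    if (rec@rs_id == cited@rs_id) next
    for (i in seq_len(nrow(variant_mentions)))
      if (validates(variant_mentions[i, ], rec)) {
        sugg <- c(sugg, rec@rs_id); break
      }
  }
  if (length(sugg)) res("inconsistent", unique(sugg)) else res("unsupported")
}

#' Normalize every mention of a document
#'
#' Runs recognition on the document text, normalizes each mention against
#' the store, and applies the rs-consistency check to rs mentions that are
#' co-mentioned with variant descriptions (an inconsistent citation gets
#' status \code{RS_INCONSISTENT} with the suggested ids in place of the
#' cited one).
#'
#' @param text document text.
#' @param gene_ids genes mentioned in the document (input; gene
#'   recognition is out of scope).
#' @param store a \linkS4class{SnpStore}.
#' @param tables symbol tables from \code{\link{alphabetTables}}.
#' @param doc_id document identifier.
#' @return data.frame with one row per mention: \code{doc_id},
#'   \code{start}, \code{end}, \code{surface}, \code{status},
#'   \code{rs_ids} (semicolon-joined) and \code{explanation}.
#' @examples
#' fx <- nos3Fixture()
#' normalizeDocument(
#'   "The Glu(298)– –>Asp (E298D; 894G– –>T) polymorphism of eNOS",
#'   gene_ids = "NOS3", store = fx$store)
#' @export
normalizeDocument <- function(text, gene_ids, store,
                              tables = alphabetTables(), doc_id = "doc1") {
  mentions <- findMentions(text, tables, doc_id)
  rows <- lapply(seq_len(nrow(mentions)), function(i) {
    m <- mentions[i, ]
    o <- normalizeMention(m, gene_ids, store)
    if (identical(as.character(m$kind), "RS")) {
      others <- mentions[mentions$kind %in% c("PSM", "NSM", "AMBIGUOUS"), ,
                         drop = FALSE]
      chk <- checkRsConsistency(m, others, gene_ids, store)
      if (chk$status == "inconsistent")
        o <- list(status = "RS_INCONSISTENT",
                  rs_ids = chk$suggested_rs_ids, matches = list(),
                  explanation = "rs citation inconsistent with description")
    }
    data.frame(doc_id = m$doc_id, start = m$start, end = m$end,
               surface = m$surface, status = o$status,
               rs_ids = paste(format(o$rs_ids, scientific = FALSE,
                                     trim = TRUE),
                              collapse = ";"),
               explanation = o$explanation, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), surface = character(),
                      status = character(), rs_ids = character(),
                      explanation = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Normalize a corpus of documents
#'
#' @param documents named character vector (doc_id to text).
#' @param gene_map named list (doc_id to character vector of gene ids).
#' @param store a \linkS4class{SnpStore}.
#' @param tables symbol tables from \code{\link{alphabetTables}}.
#' @return stacked per-document data.frames of
#'   \code{\link{normalizeDocument}}.
#' @export
normalizeCorpus <- function(documents, gene_map, store,
                            tables = alphabetTables()) {
  out <- lapply(names(documents), function(d)
    normalizeDocument(documents[[d]], gene_map[[d]], store, tables, d))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write normalization results as TSV
#'
#' @param results data.frame from \code{\link{normalizeDocument}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeNormalizationTsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
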