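#' Construct a variant record
#'
#' @param rs_id positive identifier (numeric part of the rs number).
#' @param gene_ids linked gene identifiers.
#' @param position 1-based reference position.
#' @param alleles allele set on the record's own reference strand.
#' @param orientation \code{"same"} or \code{"opposite"} relative to the
#'   linked gene's strand.
#' @param reference reference sequence accession with version.
#' @param residue_position optional precursor residue position (coding
#'   records).
#' @param residues optional one-letter residue set, present together with
#'   \code{residue_position}.
#' @return a \linkS4class{SnpRecord}.
#' @examples
#' snpRecord(1799983, "NOS3", 1994, c("G", "T"),
#'           residue_position = 298, residues = c("E", "D"))
#' @export
snpRecord <- function(rs_id, gene_ids, position, alleles,
                      orientation = "same", reference = "REF_000001.1",
                      residue_position = NA, residues = character()) {
  new("SnpRecord", rs_id = as.numeric(rs_id),
      gene_ids = as.character(gene_ids), reference = as.character(reference),
      position = as.integer(position), alleles = as.character(alleles),
      orientation = orientation,
      residue_position = as.integer(residue_position),
      residues = as.character(residues))
}

#' @rdname snpRecord
#' @param record a \linkS4class{SnpRecord}.
#' @export
rsId <- function(record) record@rs_id

#' Construct a variant record store
#'
#' @param records list of \linkS4class{SnpRecord}.
#' @param models list of \linkS4class{GeneModel}.
#' @param annotations list of \linkS4class{ProteinAnnotation}.
#' @return a \linkS4class{SnpStore}.
#' @export
snpStore <- function(records = list(), models = list(),
                     annotations = list()) {
  new("SnpStore", records = records, models = models,
      annotations = annotations)
}

STORE_SCHEMA_VERSION <- 1L

#' Load a variant record store
#'
#' The primary store format is nested JSON with a \code{schema_version}
#' field and arrays \code{records}, \code{models} and \code{annotations};
#' \code{\link{writeStore}} emits it. Schema violations raise errors
#' naming the offending element.
#'
#' @param path path to a store JSON file.
#' @return a \linkS4class{SnpStore}.
#' @export
loadStore <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- function(el, field, i, what) {
    if (is.null(el[[field]]))
      stop(sprintf("store %s: %s %d lacks field '%s'", path, what, i, field))
    el[[field]]
  }
  records <- lapply(seq_along(x$records), function(i) {
    r <- x$records[[i]]
    tryCatch(snpRecord(
      rs_id = need(r, "rs_id", i, "record"),
      gene_ids = unlist(need(r, "gene_ids", i, "record")),
      position = need(r, "position", i, "record"),
      alleles = unlist(need(r, "alleles", i, "record")),
      orientation = if (is.null(r$orientation)) "same" else r$orientation,
      reference = if (is.null(r$reference)) "REF_000001.1" else r$reference,
      residue_position = if (is.null(r$residue_position)) NA else
        r$residue_position,
      residues = if (is.null(r$residues)) character() else
        unlist(r$residues)),
      error = function(e) stop(sprintf("store %s: record %d: %s", path, i,
                                       conditionMessage(e))))
  })
  models <- lapply(seq_along(x$models), function(i) {
    m <- x$models[[i]]
    ex <- do.call(rbind, lapply(m$exons, function(p) as.integer(unlist(p))))
    tryCatch(geneModel(
      gene_id = need(m, "gene_id", i, "model"),
      symbol = if (is.null(m$symbol)) m$gene_id else m$symbol,
      reference = if (is.null(m$reference)) "REF_000001.1" else m$reference,
      strand = if (is.null(m$strand)) "+" else m$strand,
      exons = ex,
      cds_start = need(m, "cds_start", i, "model"),
      cds_end = need(m, "cds_end", i, "model")),
      error = function(e) stop(sprintf("store %s: model %d: %s", path, i,
                                       conditionMessage(e))))
  })
  annotations <- lapply(seq_along(x$annotations), function(i) {
    a <- x$annotations[[i]]
    feats <- if (length(a$features))
      do.call(rbind, lapply(a$features, function(f)
        data.frame(kind = f$kind, begin = as.integer(f$begin),
                   end = as.integer(f$end), stringsAsFactors = FALSE)))
    else NULL
    proteinAnnotation(
      protein_id = if (is.null(a$protein_id)) NA else a$protein_id,
      gene_id = need(a, "gene_id", i, "annotation"),
      initiator_met_cleaved = isTRUE(a$init_met) ||
        identical(a$init_met, 1L) || identical(a$init_met, 1),
      features = feats)
  })
  snpStore(records, models, annotations)
}

#' Write a variant record store as JSON
#'
#' @param store a \linkS4class{SnpStore}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeStore <- function(store, path) {
  asRec <- function(r) {
    out <- list(rs_id = r@rs_id, gene_ids = as.list(r@gene_ids),
                reference = r@reference, position = r@position,
                alleles = as.list(r@alleles), orientation = r@orientation)
    if (!is.na(r@residue_position)) {
      out$residue_position <- r@residue_position
      out$residues <- as.list(r@residues)
    }
    out
  }
  asMod <- function(m)
    list(gene_id = m@gene_id, symbol = m@symbol, reference = m@reference,
         strand = m@strand,
         exons = lapply(seq_along(m@exons), function(i)
           c(IRanges::start(m@exons)[i], IRanges::end(m@exons)[i])),
         cds_start = m@cds_start, cds_end = m@cds_end)
  asAnn <- function(a)
    list(protein_id = a@protein_id, gene_id = a@gene_id,
         init_met = a@initiator_met_cleaved,
         features = lapply(seq_len(nrow(a@features)), function(i)
           list(kind = a@features$kind[i], begin = a@features$begin[i],
                end = a@features$end[i])))
  obj <- list(schema_version = STORE_SCHEMA_VERSION,
              records = lapply(store@records, asRec),
              models = lapply(store@models, asMod),
              annotations = lapply(store@annotations, asAnn))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read/write variant records as flat TSV
#'
#' Secondary store format: one record per row with comma-joined set
#' fields. Columns: \code{rs_id}, \code{gene_ids}, \code{reference},
#' \code{position}, \code{alleles}, \code{orientation},
#' \code{residue_position}, \code{residues}.
#'
#' @param path TSV file path.
#' @return \code{readSnpRecordsTsv}: list of \linkS4class{SnpRecord}.
#' @export
readSnpRecordsTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  lapply(seq_len(nrow(df)), function(i) {
    tryCatch(snpRecord(
      rs_id = df$rs_id[i],
      gene_ids = strsplit(df$gene_ids[i], ",")[[1]],
      reference = df$reference[i], position = df$position[i],
      alleles = strsplit(df$alleles[i], ",")[[1]],
      orientation = df$orientation[i],
      residue_position = df$residue_position[i],
      residues = if (is.na(df$residues[i])) character() else
        strsplit(df$residues[i], ",")[[1]]),
      error = function(e) stop(sprintf("%s line %d: %s", path, i + 1L,
                                       conditionMessage(e))))
  })
}

#' @rdname readSnpRecordsTsv
#' @param records list of \linkS4class{SnpRecord}.
#' @export
writeSnpRecordsTsv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(rs_id = r@rs_id, gene_ids = paste(r@gene_ids, collapse = ","),
               reference = r@reference, position = r@position,
               alleles = paste(r@alleles, collapse = ","),
               orientation = r@orientation,
               residue_position = r@residue_position,
               residues = if (length(r@residues))
                 paste(r@residues, collapse = ",") else NA,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read protein annotations from TSV
#'
#' Feature-table-like rows: columns \code{protein_id}, \code{gene_id},
#' \code{init_met} (0/1) and \code{features} (semicolon-joined
#' \code{kind:begin-end} triplets, may be empty).
#'
#' @param path TSV file path.
#' @return list of \linkS4class{ProteinAnnotation}.
#' @export
readProteinAnnotationsTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  lapply(seq_len(nrow(df)), function(i) {
    feats <- NULL
    if (!is.na(df$features[i]) && nzchar(df$features[i])) {
      parts <- strsplit(df$features[i], ";", fixed = TRUE)[[1]]
      m <- regmatches(parts, regexec("^([A-Za-z_]+):([0-9]+)-([0-9]+)$",
                                     parts))
      bad <- which(vapply(m, length, integer(1)) == 0L)
      if (length(bad))
        stop(sprintf("%s line %d: malformed feature '%s'", path, i + 1L,
                     parts[bad[1]]))
      feats <- data.frame(kind = vapply(m, `[`, "", 2L),
                          begin = as.integer(vapply(m, `[`, "", 3L)),
                          end = as.integer(vapply(m, `[`, "", 4L)),
                          stringsAsFactors = FALSE)
    }
    proteinAnnotation(df$protein_id[i], df$gene_id[i],
                      initiator_met_cleaved = df$init_met[i] %in% c(1, "1", TRUE),
                      features = feats)
  })
}

# store accessors -----------------------------------------------------------

#' Accessors for a variant record store
#'
#' @param store a \linkS4class{SnpStore}.
#' @return \code{storeRecords}/\code{storeModels}/\code{storeAnnotations}:
#'   the respective component lists.
#' @export
storeRecords <- function(store) store@records

#' @rdname storeRecords
#' @export
storeModels <- function(store) store@models

#' @rdname storeRecords
#' @export
storeAnnotations <- function(store) store@annotations

modelsForGenes <- function(store, gene_ids) {
  Filter(function(m) m@gene_id %in% gene_ids, store@models)
}

annotationForGenes <- function(store, gene_ids) {
  hit <- Filter(function(a) a@gene_id %in% gene_ids, store@annotations)
  if (length(hit)) hit[[1L]] else proteinAnnotation()
}

recordByRsId <- function(store, rs_id) {
  hit <- Filter(function(r) r@rs_id == rs_id, store@records)
  if (length(hit)) hit[[1L]] else NULL
}
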