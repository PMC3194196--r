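#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param symbol gene symbol (defaults to \code{gene_id}).
#' @param reference reference sequence accession with version.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons two-column matrix or list of \code{c(start, end)} pairs of
#'   exon intervals in 1-based closed reference coordinates, or an
#'   \code{IRanges}.
#' @param cds_start reference position of the A of the start codon.
#' @param cds_end reference position of the last base of the stop codon.
#' @param tss reference position of the transcription start; defaults to
#'   the gene-strand-first exonic base.
#' @return a \linkS4class{GeneModel}.
#' @examples
#' gm <- geneModel("g1", exons = list(c(101, 200), c(301, 400)),
#'                 cds_start = 151, cds_end = 350)
#' @export
geneModel <- function(gene_id, symbol = gene_id, reference = "REF_000001.1",
                      strand = "+", exons, cds_start, cds_end, tss = NULL) {
  if (is(exons, "IRanges")) {
    ir <- exons
  } else {
    if (is.list(exons)) exons <- do.call(rbind, exons)
    ir <- IRanges::IRanges(start = as.integer(exons[, 1]),
                           end = as.integer(exons[, 2]))
  }
  ir <- ir[order(IRanges::start(ir))]
  if (is.null(tss))
    tss <- if (strand == "+") min(IRanges::start(ir)) else
      max(IRanges::end(ir))
  new("GeneModel", gene_id = as.character(gene_id),
      symbol = as.character(symbol), reference = as.character(reference),
      strand = strand, exons = ir, cds_start = as.integer(cds_start),
      cds_end = as.integer(cds_end), tss = as.integer(tss))
}

#' @rdname geneModel
#' @param model a \linkS4class{GeneModel}.
#' @export
geneId <- function(model) model@gene_id

#' @rdname geneModel
#' @export
geneSymbol <- function(model) model@symbol

#' @rdname geneModel
#' @export
exonRanges <- function(model) model@exons

#' @rdname geneModel
#' @export
geneStrand <- function(model) model@strand

# --- internal gene-strand ("walk") geometry -------------------------------
#
# All scheme arithmetic is done in a signed walk coordinate u in which the
# gene strand runs in increasing u regardless of the reference strand:
# u = gpos on "+" genes and u = -gpos on "-" genes. Exons are re-expressed
# as ascending u-intervals in transcript (5'->3') order.

modelGeometry <- function(model) {
  st <- IRanges::start(model@exons); en <- IRanges::end(model@exons)
  if (model@strand == "+") {
    us <- st; ue <- en
  } else {
    ord <- order(-en)
    us <- -en[ord]; ue <- -st[ord]
  }
  w <- ue - us + 1L
  cum <- cumsum(c(0L, w[-length(w)]))
  toU <- if (model@strand == "+") identity else function(g) -g
  fromU <- toU
  u_tss <- toU(model@tss)
  geo <- list(us = us, ue = ue, w = w, cum = cum, toU = toU, fromU = fromU,
              u_tss = u_tss, n_exon = length(us),
              transcript_length = sum(w))
  geo$tpos <- function(u) {       # transcript position of an exonic u
    i <- which(u >= us & u <= ue)
    if (!length(i)) NA_integer_ else cum[i] + (u - us[i] + 1L)
  }
  geo$uOfTpos <- function(tp) {   # inverse of tpos
    if (is.na(tp) || tp < 1L || tp > geo$transcript_length)
      return(NA_integer_)
    i <- findInterval(tp, cum + 1L)
    us[i] + (tp - cum[i] - 1L)
  }
  geo$t_atg <- geo$tpos(toU(model@cds_start))
  geo$t_stop <- geo$tpos(toU(model@cds_end))
  geo
}

# locate a walk coordinate: exonic (with tpos), intronic (with intron
# ordinal and distances to both flanking exon edges), upstream of the cap
# or downstream of the transcript
locateU <- function(geo, u) {
  if (u < geo$us[1L])
    return(list(where = "upstream", dist = geo$us[1L] - u))
  if (u > geo$ue[geo$n_exon])
    return(list(where = "downstream", dist = u - geo$ue[geo$n_exon]))
  for (i in seq_len(geo$n_exon)) {
    if (u >= geo$us[i] && u <= geo$ue[i])
      return(list(where = "exon", exon = i, tpos = geo$cum[i] +
                    (u - geo$us[i] + 1L)))
    if (i < geo$n_exon && u > geo$ue[i] && u < geo$us[i + 1L])
      return(list(where = "intron", intron = i,
                  d5 = u - geo$ue[i],            # from 5' exon end
                  d3 = geo$us[i + 1L] - u))      # to 3' exon start
  }
  stop("locateU: unreachable")
}

#' Read gene models from a flat TSV
#'
#' Columns: \code{gene_id}, \code{symbol}, \code{accession},
#' \code{strand}, \code{exons} (semicolon-separated \code{start-end}
#' pairs), \code{cds_start}, \code{cds_end}. One row per transcript.
#'
#' @param path TSV file path.
#' @return list of \linkS4class{GeneModel}.
#' @export
readGeneModelsTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_id", "symbol", "accession", "strand", "exons",
            "cds_start", "cds_end")
  if (!all(need %in% names(df)))
    stop("gene model TSV needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    pairs <- strsplit(strsplit(df$exons[i], ";", fixed = TRUE)[[1]], "-",
                      fixed = TRUE)
    ex <- do.call(rbind, lapply(pairs, as.integer))
    geneModel(df$gene_id[i], df$symbol[i], df$accession[i], df$strand[i],
              ex, as.integer(df$cds_start[i]), as.integer(df$cds_end[i]))
  })
}

#' Write gene models to a flat TSV
#'
#' @param models list of \linkS4class{GeneModel}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGeneModelsTsv <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(gene_id = m@gene_id, symbol = m@symbol,
               reference = m@reference, strand = m@strand,
               exons = paste(sprintf("%d-%d", IRanges::start(m@exons),
                                     IRanges::end(m@exons)), collapse = ";"),
               cds_start = m@cds_start, cds_end = m@cds_end,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "reference"] <- "accession"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects \code{gene}/\code{mRNA}/\code{exon}/\code{CDS} features with
#' \code{ID}/\code{Parent} attributes; one model is built per mRNA. The
#' start codon is taken as the gene-strand-first CDS base and the CDS end
#' as the gene-strand-last CDS base.
#'
#' @param path GFF3 file path.
#' @return list of \linkS4class{GeneModel}.
#' @export
readGeneModelsGff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("readGeneModelsGff3 requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr$Parent <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  mrna <- gr[gr$type == "mRNA", , drop = FALSE]
  lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    kids <- gr[!is.na(gr$Parent) & gr$Parent == tid, , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    strand <- as.character(mrna$strand[i])
    cs <- if (strand == "+") min(cds$start) else max(cds$end)
    ce <- if (strand == "+") max(cds$end) else min(cds$start)
    gid <- if (!is.na(mrna$Parent[i])) mrna$Parent[i] else tid
    geneModel(gene_id = gid, symbol = tid,
              reference = as.character(mrna$seqnames[i]), strand = strand,
              exons = cbind(ex$start, ex$end),
              cds_start = cs, cds_end = ce)
  })
}
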