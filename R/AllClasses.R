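#' @import methods
#' @importFrom IRanges IRanges
NULL

POSITION_SCHEMES <- c("LEGACY1993", "GENOMIC", "IVS", "HGVS_C")
POSITION_REGIONS <- c("UPSTREAM", "FIVE_UTR", "CDS", "INTRON", "THREE_UTR",
                      "GENOMIC")
MENTION_KINDS    <- c("PSM", "NSM", "RS", "AMBIGUOUS")
OUTCOME_STATUSES <- c("UNIQUE", "AMBIGUOUS_DUPLICATE", "MULTIPLE_GENES",
                      "NO_MATCH", "RS_DIRECT", "RS_INCONSISTENT")
NUCLEOTIDES      <- c("A", "C", "G", "T")

#' Scheme-tagged variant position expression
#'
#' A coordinate under one of the four human-mutation nomenclature
#' conventions: \code{LEGACY1993} (transcript numbering from the 5' cap
#' site), \code{GENOMIC} (absolute 1-based reference numbering),
#' \code{IVS} (exonic numbering from the A of the start codon with
#' \code{IVSn+d} intronic forms) and \code{HGVS_C} (coding-DNA "c."
#' numbering with negative 5'UTR and asterisk 3'UTR positions).
#'
#' @slot scheme one of \code{LEGACY1993}, \code{GENOMIC}, \code{IVS},
#'   \code{HGVS_C}.
#' @slot region one of \code{UPSTREAM}, \code{FIVE_UTR}, \code{CDS},
#'   \code{INTRON}, \code{THREE_UTR}, \code{GENOMIC}.
#' @slot anchor signed integer anchor (transcript, coding or genomic
#'   coordinate; the asterisk number for \code{THREE_UTR} under
#'   \code{HGVS_C}; \code{NA} for intronic IVS forms, which are anchored
#'   by the intron ordinal instead).
#' @slot offset signed intronic offset (0 for exonic positions).
#' @slot ivs_index intron ordinal, IVS intronic forms only.
#' @slot star whether the anchor is a 3'UTR asterisk number
#'   (\code{HGVS_C} only; distinguishes \code{c.*26+2} from \code{c.26+2}).
#' @export
setClass("PositionExpression",
  representation(scheme = "character", region = "character",
                 anchor = "integer", offset = "integer",
                 ivs_index = "integer", star = "logical"),
  prototype(scheme = "GENOMIC", region = "GENOMIC", anchor = NA_integer_,
            offset = 0L, ivs_index = NA_integer_, star = FALSE))

setValidity("PositionExpression", function(object) {
  msg <- character()
  if (!object@scheme %in% POSITION_SCHEMES)
    msg <- c(msg, sprintf("unknown scheme '%s'", object@scheme))
  if (!object@region %in% POSITION_REGIONS)
    msg <- c(msg, sprintf("unknown region '%s'", object@region))
  if (!is.na(object@anchor) && object@anchor == 0L &&
      object@scheme != "GENOMIC")
    msg <- c(msg, "position zero is not defined in this scheme")
  if (object@star && object@scheme != "HGVS_C")
    msg <- c(msg, "asterisk anchors exist only in HGVS_C")
  if (object@star && (is.na(object@anchor) || object@anchor < 1L))
    msg <- c(msg, "asterisk anchors count from *1")
  if (object@region == "INTRON" && identical(object@offset, 0L))
    msg <- c(msg, "intronic expression must carry a nonzero offset")
  if (object@scheme == "IVS" && object@region == "INTRON" &&
      is.na(object@ivs_index))
    msg <- c(msg, "intronic IVS expression requires an intron ordinal")
  if (length(msg)) msg else TRUE
})

#' Gene model on a versioned reference sequence
#'
#' Exon structure, strand and CDS bounds of one transcript, in 1-based
#' closed reference coordinates. All four position-numbering conventions
#' are computed from this object. Exons are stored in reference order;
#' transcript order follows the gene strand (antiparallel to the reference
#' for minus-strand genes).
#'
#' @slot gene_id gene identifier (e.g. an Entrez-style id).
#' @slot symbol gene symbol.
#' @slot reference reference sequence accession with version.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons \code{IRanges} of exon intervals on the reference.
#' @slot cds_start reference position of the A of the start codon
#'   (first base of the start codon on the gene strand).
#' @slot cds_end reference position of the last base of the stop codon
#'   on the gene strand.
#' @slot tss reference position of the transcription start (5' cap).
#' @export
setClass("GeneModel",
  representation(gene_id = "character", symbol = "character",
                 reference = "character", strand = "character",
                 exons = "IRanges", cds_start = "integer",
                 cds_end = "integer", tss = "integer"))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) {
    msg <- c(msg, "gene model needs at least one exon")
    return(msg)
  }
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (is.unsorted(st, strictly = TRUE) ||
      any(st[-1] <= en[-length(en)]))
    msg <- c(msg, "exons must be sorted and non-overlapping on the reference")
  first5 <- if (object@strand == "+") st[1L] else en[length(en)]
  if (!identical(as.integer(object@tss), as.integer(first5)))
    msg <- c(msg, "tss must be the gene-strand-first exonic base")
  inExon <- function(p) any(p >= st & p <= en)
  if (!inExon(object@cds_start)) msg <- c(msg, "cds_start must be exonic")
  if (!inExon(object@cds_end))   msg <- c(msg, "cds_end must be exonic")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s) on %s strand %s\n", object@gene_id,
              object@symbol, object@reference, object@strand))
  cat(sprintf("  %d exon(s): %s\n", length(object@exons),
              paste(sprintf("[%d,%d]", IRanges::start(object@exons),
                            IRanges::end(object@exons)), collapse = " ")))
  cat(sprintf("  tss=%d cds=[%d,%d]\n", object@tss, object@cds_start,
              object@cds_end))
})

#' dbSNP-style variant record
#'
#' One refSNP-cluster-like record: identifier, linked genes, reference
#' position, the allele set as stored on the record's own reference strand,
#' and the orientation of that strand relative to the linked gene. Coding
#' records may additionally carry the residue position (precursor
#' coordinates) and residue set.
#'
#' @slot rs_id positive refSNP-style identifier (numeric part only).
#' @slot gene_ids identifiers of linked genes.
#' @slot reference reference sequence accession with version.
#' @slot position 1-based reference position.
#' @slot alleles nucleotide allele set on the record's own strand.
#' @slot orientation \code{"same"} or \code{"opposite"} relative to the
#'   linked gene's strand; \code{"opposite"} means the stored alleles must
#'   be complemented before comparison with gene-strand mentions.
#' @slot residue_position optional precursor-coordinate residue position.
#' @slot residues optional one-letter residue set (present together with
#'   \code{residue_position}).
#' @export
setClass("SnpRecord",
  representation(rs_id = "numeric", gene_ids = "character",
                 reference = "character", position = "integer",
                 alleles = "character", orientation = "character",
                 residue_position = "integer", residues = "character"),
  prototype(residue_position = NA_integer_, residues = character()))

setValidity("SnpRecord", function(object) {
  msg <- character()
  if (length(object@rs_id) != 1L || is.na(object@rs_id) || object@rs_id < 1)
    msg <- c(msg, "rs_id must be a single positive number")
  if (!all(object@alleles %in% NUCLEOTIDES))
    msg <- c(msg, "alleles must be nucleotides A/C/G/T")
  if (length(unique(object@alleles)) < 2L)
    msg <- c(msg, "a variant record needs at least two alleles")
  if (!object@orientation %in% c("same", "opposite"))
    msg <- c(msg, "orientation must be 'same' or 'opposite'")
  hasPos <- !is.na(object@residue_position)
  hasRes <- length(object@residues) > 0L
  if (hasPos != hasRes)
    msg <- c(msg, "residue_position and residues must be present together")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SnpRecord", function(object) {
  res <- if (is.na(object@residue_position)) "" else
    sprintf(" residues %s@%d", paste(object@residues, collapse = "/"),
            object@residue_position)
  cat(sprintf("SnpRecord rs%.0f %s:%d %s (%s)%s genes=%s\n", object@rs_id,
              object@reference, object@position,
              paste(object@alleles, collapse = "/"), object@orientation,
              res, paste(object@gene_ids, collapse = ",")))
})

#' Protein annotation for systematic-offset recovery
#'
#' UniProt-feature-like annotation of one protein: whether the initiator
#' methionine is cleaved, and maturation features (Signal, Transit,
#' Peptide, Propeptide, Var_seq) in precursor coordinates. Used to explain
#' constant offsets between mature-protein residue numbering in text and
#' precursor numbering in variant records.
#'
#' @slot protein_id protein accession.
#' @slot gene_id linked gene identifier.
#' @slot initiator_met_cleaved whether the initiator Met is removed
#'   post-translationally (+1 offset between mature and precursor
#'   numbering).
#' @slot features data.frame with columns \code{kind}, \code{begin},
#'   \code{end} (precursor residue coordinates).
#' @export
setClass("ProteinAnnotation",
  representation(protein_id = "character", gene_id = "character",
                 initiator_met_cleaved = "logical",
                 features = "data.frame"),
  prototype(protein_id = NA_character_, gene_id = NA_character_,
            initiator_met_cleaved = FALSE,
            features = data.frame(kind = character(), begin = integer(),
                                  end = integer())))

setValidity("ProteinAnnotation", function(object) {
  msg <- character()
  f <- object@features
  if (!all(c("kind", "begin", "end") %in% names(f)))
    msg <- c(msg, "features needs columns kind, begin, end")
  else {
    ok <- c("Signal", "Transit", "Peptide", "Propeptide", "Var_seq")
    if (!all(f$kind %in% ok))
      msg <- c(msg, sprintf("feature kind must be one of %s",
                            paste(ok, collapse = ", ")))
    if (any(f$begin < 1L) || any(f$end < f$begin))
      msg <- c(msg, "feature intervals need 1 <= begin <= end")
  }
  if (length(msg)) msg else TRUE
})

#' Outcome of validating one mention against one record
#'
#' @slot matched whether position and alleles/residues both validated.
#' @slot rs_id the record's identifier when matched.
#' @slot scheme nomenclature scheme under which the position validated
#'   (NSM paths; \code{NA} for PSM paths).
#' @slot offset_provenance \code{"NONE"}, \code{"INIT_MET"} or
#'   \code{"FEATURE"} (PSM paths).
#' @slot offset_delta signed residue offset applied (PSM paths).
#' @slot offset_feature feature label backing a \code{FEATURE} offset.
#' @slot strand_flipped whether record alleles were complemented before
#'   comparison (NSM paths only).
#' @slot direction_flipped whether the match required swapping the
#'   mention's wild-type/mutated order relative to the record.
#' @slot transcript gene model (gene_id of the transcript) that validated
#'   the position, NSM paths.
#' @export
setClass("MatchResult",
  representation(matched = "logical", rs_id = "numeric",
                 scheme = "character", offset_provenance = "character",
                 offset_delta = "integer", offset_feature = "character",
                 strand_flipped = "logical", direction_flipped = "logical",
                 transcript = "character"),
  prototype(matched = FALSE, rs_id = NA_real_, scheme = NA_character_,
            offset_provenance = NA_character_, offset_delta = NA_integer_,
            offset_feature = NA_character_, strand_flipped = FALSE,
            direction_flipped = FALSE, transcript = NA_character_))

setValidity("MatchResult", function(object) {
  if (!object@matched && !is.na(object@rs_id))
    "an unmatched result cannot carry an rs_id" else TRUE
})

setMethod("show", "MatchResult", function(object) {
  if (!object@matched) { cat("MatchResult: no match\n"); return(invisible()) }
  bits <- c(sprintf("rs%.0f", object@rs_id))
  if (!is.na(object@scheme)) bits <- c(bits, paste0("scheme=", object@scheme))
  if (!is.na(object@offset_provenance) && object@offset_provenance != "NONE")
    bits <- c(bits, sprintf("offset=%s(%+d)", object@offset_provenance,
                            object@offset_delta))
  if (object@strand_flipped)    bits <- c(bits, "strand=flip")
  if (object@direction_flipped) bits <- c(bits, "direction=flip")
  cat("MatchResult:", paste(bits, collapse = " "), "\n")
})

#' Variant record store
#'
#' Container bundling variant records, gene models and protein annotations,
#' the abstraction boundary emulating a SNP database snapshot plus its gene
#' and protein annotation sources.
#'
#' @slot records list of \linkS4class{SnpRecord}.
#' @slot models list of \linkS4class{GeneModel} (several transcripts per
#'   gene are allowed).
#' @slot annotations list of \linkS4class{ProteinAnnotation}.
#' @export
setClass("SnpStore",
  representation(records = "list", models = "list", annotations = "list"),
  prototype(records = list(), models = list(), annotations = list()))

setValidity("SnpStore", function(object) {
  msg <- character()
  if (!all(vapply(object@records, is, logical(1), "SnpRecord")))
    msg <- c(msg, "records must all be SnpRecord")
  if (!all(vapply(object@models, is, logical(1), "GeneModel")))
    msg <- c(msg, "models must all be GeneModel")
  if (!all(vapply(object@annotations, is, logical(1), "ProteinAnnotation")))
    msg <- c(msg, "annotations must all be ProteinAnnotation")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SnpStore", function(object) {
  cat(sprintf("SnpStore: %d record(s), %d gene model(s), %d annotation(s)\n",
              length(object@records), length(object@models),
              length(object@annotations)))
})
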