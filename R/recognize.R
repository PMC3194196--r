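MENTION_COLUMNS <- c("doc_id", "start", "end", "surface", "kind", "wild",
                     "mutated", "position_text", "accession", "rs_number",
                     "scheme_hint")

emptyMentions <- function() {
  data.frame(doc_id = character(), start = integer(), end = integer(),
             surface = character(), kind = character(), wild = character(),
             mutated = character(), position_text = character(),
             accession = character(), rs_number = numeric(),
             scheme_hint = character(), stringsAsFactors = FALSE)
}

mentionRow <- function(doc_id, cstart, cend, kind, wild = "", mutated = "",
                       position_text = "", accession = "", rs_number = NA_real_,
                       scheme_hint = "") {
  data.frame(doc_id = doc_id, start = cstart, end = cend, surface = "",
             kind = kind, wild = wild, mutated = mutated,
             position_text = position_text, accession = accession,
             rs_number = rs_number, scheme_hint = scheme_hint,
             stringsAsFactors = FALSE)
}

# run a perl regex with capture groups; one row per match
reFind <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), end = integer(), match = character()))
  len <- attr(m, "match.length")
  cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
  out <- data.frame(start = as.integer(m), end = as.integer(m + len - 1L),
                    match = substring(text, m, m + len - 1L),
                    stringsAsFactors = FALSE)
  if (!is.null(cs)) {
    for (j in seq_len(ncol(cs))) {
      g <- ifelse(cs[, j] > 0L,
                  substring(text, cs[, j], cs[, j] + cl[, j] - 1L), "")
      out[[paste0("g", j)]] <- g
    }
  }
  out
}

AA3_ALT  <- paste(names(AA_THREE_TO_ONE), collapse = "|")
TERM_ALT <- "term|amber|opal|ochre|Ter|Stop|stop"

mapResidue3 <- function(x) {
  if (x %in% names(AA_THREE_TO_ONE)) unname(AA_THREE_TO_ONE[x]) else "*"
}

#' Detect protein-level variant mentions
#'
#' Finds protein sequence mutation (PSM) mentions in one-letter
#' (\code{E298D}), three-letter (\code{Glu298Asp}), bracketed or arrowed
#' (\code{Glu(298)>Asp}) and \code{p.}-prefixed forms. Termination
#' spellings (\code{Ter}, \code{X}, \code{*}, \code{term}, \code{amber},
#' \code{opal}, \code{ochre}) are accepted as mutated residue and mapped to
#' the stop sentinel \code{"*"}; the ambiguous \code{Xle} code maps to
#' \code{J}. Surfaces on the stoplist (cell lines, transcription factors,
#' ...) are never emitted. A one-letter mention whose residues are both
#' nucleotide symbols is emitted with kind \code{AMBIGUOUS}, since it may
#' equally describe a nucleotide-level variant.
#'
#' @param text document text (canonicalized internally; spans refer to the
#'   original text, 0-based half-open).
#' @param tables symbol tables from \code{\link{alphabetTables}}.
#' @param doc_id document identifier for the standoff output.
#' @return standoff data.frame of mentions (see \code{\link{findMentions}}).
#' @export
findProteinMentions <- function(text, tables = alphabetTables(),
                                doc_id = "doc1") {
  ct <- canonicalizeText(text)
  out <- list()
  # three-letter forms, optional brackets/arrow/p. prefix
  pat3 <- sprintf("(?:p\\.)?\\b(%s)\\(?(\\d+)\\)?(?: ?> ?)?(%s|%s|X|\\*)",
                  AA3_ALT, AA3_ALT, TERM_ALT)
  hits <- reFind(ct$text, pat3)
  for (i in seq_len(nrow(hits))) {
    out[[length(out) + 1L]] <- mentionRow(
      doc_id, hits$start[i], hits$end[i], kind = "PSM",
      wild = mapResidue3(hits$g1[i]), mutated = mapResidue3(hits$g3[i]),
      position_text = hits$g2[i])
  }
  # one-letter forms
  pat1 <- "(p\\.)?\\b([A-Z])(\\d+)([A-Z]\\b|\\*)"
  hits <- reFind(ct$text, pat1)
  for (i in seq_len(nrow(hits))) {
    w <- hits$g2[i]; mu <- hits$g4[i]
    if (!w %in% AA_ONE) next
    if (mu == "X") mu <- "*"
    if (!(mu %in% AA_ONE || mu == "*")) next
    if (hits$match[i] %in% tables$stoplist) next
    ambiguous <- !nzchar(hits$g1[i]) && w %in% NUCLEOTIDES &&
      mu %in% NUCLEOTIDES
    out[[length(out) + 1L]] <- mentionRow(
      doc_id, hits$start[i], hits$end[i],
      kind = if (ambiguous) "AMBIGUOUS" else "PSM",
      wild = w, mutated = mu, position_text = hits$g3[i])
  }
  finalizeMentions(out, text, ct, tables)
}

#' Detect nucleotide-level variant mentions
#'
#' Finds nucleotide sequence mutation (NSM) mentions in legacy transcript
#' numbering (\code{894G>T}, \code{-225C>A}, \code{252+2T>C}), IVS
#' intronic notation (\code{IVS2+2T>C}), prefixed HGVS-style forms
#' (\code{c.26+2T>C}, \code{g.-420C>G}, optionally with a reference
#' accession as in \code{NM_005957.3:c.123G>T}) and multi-allele forms
#' (\code{82C>T/G}). The position expression is preserved verbatim in
#' \code{position_text} (sign, anchor, offset); a \code{c.}/\code{g.}/
#' \code{r.} prefix is recorded in \code{scheme_hint}.
#'
#' @inheritParams findProteinMentions
#' @return standoff data.frame of mentions (see \code{\link{findMentions}}).
#' @export
findNucleotideMentions <- function(text, tables = alphabetTables(),
                                   doc_id = "doc1") {
  ct <- canonicalizeText(text)
  out <- list()
  splitAlleles <- function(x) toupper(strsplit(x, "/", fixed = TRUE)[[1]])
  # scheme-prefixed (HGVS-style), optional accession
  patP <- paste0("(?:([A-Z]{2}_\\d+(?:\\.\\d+)?):)?\\b([cgr])\\.",
                 "(\\*?-?\\d+(?:[+-]\\d+)?)",
                 "([ACGTUacgtu])>([ACGTUacgtu](?:/[ACGTUacgtu])*)")
  hits <- reFind(ct$text, patP)
  for (i in seq_len(nrow(hits))) {
    out[[length(out) + 1L]] <- mentionRow(
      doc_id, hits$start[i], hits$end[i], kind = "NSM",
      wild = toupper(hits$g4[i]),
      mutated = paste(splitAlleles(hits$g5[i]), collapse = ","),
      position_text = hits$g3[i], accession = hits$g1[i],
      scheme_hint = paste0(hits$g2[i], "."))
  }
  # IVS intronic forms
  patI <- "\\bIVS(\\d+)([+-]\\d+)([ACGT])>([ACGT](?:/[ACGT])*)"
  hits <- reFind(ct$text, patI)
  for (i in seq_len(nrow(hits))) {
    out[[length(out) + 1L]] <- mentionRow(
      doc_id, hits$start[i], hits$end[i], kind = "NSM",
      wild = hits$g3[i],
      mutated = paste(splitAlleles(hits$g4[i]), collapse = ","),
      position_text = paste0("IVS", hits$g1[i], hits$g2[i]))
  }
  # unprefixed legacy / bare-number / signed / two-number forms
  patL <- "(\\*?-?\\d+(?:[+-]\\d+)?)([ACGT])>([ACGT](?:/[ACGT])*)"
  hits <- reFind(ct$text, patL)
  for (i in seq_len(nrow(hits))) {
    out[[length(out) + 1L]] <- mentionRow(
      doc_id, hits$start[i], hits$end[i], kind = "NSM",
      wild = hits$g2[i],
      mutated = paste(splitAlleles(hits$g3[i]), collapse = ","),
      position_text = hits$g1[i])
  }
  # allele-first signed forms like G-2548A
  patF <- "\\b([ACGT])(-\\d+)([ACGT])\\b"
  hits <- reFind(ct$text, patF)
  for (i in seq_len(nrow(hits))) {
    out[[length(out) + 1L]] <- mentionRow(
      doc_id, hits$start[i], hits$end[i], kind = "NSM",
      wild = hits$g1[i], mutated = hits$g3[i],
      position_text = hits$g2[i])
  }
  finalizeMentions(out, text, ct, tables)
}

#' Detect rs-identifier mentions
#'
#' Matches the pattern \code{[rR][sS][ ]*[1-9][0-9]*}. A match whose "rs"
#' is capitalized (\code{RS}, \code{Rs}, \code{rS}) is kept only when at
#' least one trigger keyword (e.g. "mutation", "SNP", "polymorphism")
#' occurs somewhere in the document and no exclusion word (e.g. "strain")
#' does; this removes product names such as "RS6000". Surfaces on the rs
#' blacklist of known false positives are always rejected.
#'
#' @inheritParams findProteinMentions
#' @return standoff data.frame of mentions (see \code{\link{findMentions}}).
#' @export
findRsMentions <- function(text, tables = alphabetTables(),
                           doc_id = "doc1") {
  ct <- canonicalizeText(text)
  hasWord <- function(words)
    any(vapply(words, function(w)
      grepl(paste0("(?i)\\b", w, "\\b"), ct$text, perl = TRUE), logical(1)))
  keywordOk <- hasWord(tables$rs_keywords) && !hasWord(tables$rs_exclusions)
  out <- list()
  hits <- reFind(ct$text, "\\b([rR][sS]) *([1-9][0-9]*)\\b")
  for (i in seq_len(nrow(hits))) {
    canon <- paste0("rs", hits$g2[i])
    if (canon %in% tables$rs_blacklist) next
    if (hits$g1[i] != "rs" && !keywordOk) next
    out[[length(out) + 1L]] <- mentionRow(
      doc_id, hits$start[i], hits$end[i], kind = "RS",
      rs_number = as.numeric(hits$g2[i]))
  }
  finalizeMentions(out, text, ct, tables)
}

# map canonical spans back to the original text, resolve overlaps
# longest-match-first (ties leftmost), emit 0-based half-open offsets
finalizeMentions <- function(rows, text, ct, tables, resolve = TRUE) {
  if (!length(rows)) return(emptyMentions())
  df <- do.call(rbind, rows)
  if (resolve) {
    len <- df$end - df$start + 1L
    ord <- order(-len, df$start)
    keep <- logical(nrow(df))
    taken <- rep(FALSE, nchar(ct$text))
    for (i in ord) {
      span <- seq.int(df$start[i], df$end[i])
      if (!any(taken[span])) { keep[i] <- TRUE; taken[span] <- TRUE }
    }
    df <- df[keep, , drop = FALSE]
  }
  ostart <- ct$map[df$start]
  oend <- ct$map[df$end]
  df$surface <- substring(text, ostart, oend)
  df$start <- ostart - 1L
  df$end <- as.integer(oend)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df[, MENTION_COLUMNS]
}

#' Detect all variant mentions in a document
#'
#' Runs the protein-level, nucleotide-level and rs-identifier finders on
#' the canonicalized text and resolves overlapping candidates
#' longest-match-first (ties broken by leftmost start), so e.g.
#' \code{NM_005957.3:c.123G>T} is reported once as a prefixed NSM rather
#' than additionally as its unprefixed suffix.
#'
#' @inheritParams findProteinMentions
#' @return a standoff data.frame with one row per mention and columns
#'   \code{doc_id}, \code{start}, \code{end} (0-based half-open character
#'   offsets on the original text), \code{surface}, \code{kind}
#'   (\code{PSM}/\code{NSM}/\code{RS}/\code{AMBIGUOUS}), \code{wild},
#'   \code{mutated} (comma-separated for multi-allele forms),
#'   \code{position_text}, \code{accession}, \code{rs_number} and
#'   \code{scheme_hint}.
#' @examples
#' findMentions("The Glu(298)– –>Asp (E298D; 894G– –>T) polymorphism")
#' @export
findMentions <- function(text, tables = alphabetTables(), doc_id = "doc1") {
  ct <- canonicalizeText(text)
  parts <- rbind(
    findNucleotideMentions(text, tables, doc_id),
    findProteinMentions(text, tables, doc_id),
    findRsMentions(text, tables, doc_id))
  if (nrow(parts) == 0L) return(parts)
  # finders already resolved internally; resolve across finders on the
  # original-coordinate spans (longest first, ties leftmost)
  len <- parts$end - parts$start
  ord <- order(-len, parts$start)
  keep <- logical(nrow(parts))
  taken <- rep(FALSE, nchar(text))
  for (i in ord) {
    span <- seq.int(parts$start[i] + 1L, parts$end[i])
    if (!any(taken[span])) { keep[i] <- TRUE; taken[span] <- TRUE }
  }
  out <- parts[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the sequence level of a mention
#'
#' Decides whether a mention describes a protein-level variant
#' (\code{PSM}), a nucleotide-level variant (\code{NSM}) or could be
#' either (\code{BOTH}, in which case the normalizer pursues both
#' validation paths). Three-letter and \code{p.}-prefixed surfaces are
#' protein-level; \code{c.}/\code{g.}/\code{r.} prefixes, IVS forms and
#' signed or two-number positions are nucleotide-level. For the remaining
#' ambiguous one-letter A/C/G/T mentions the position heuristic applies:
#' almost all annotated protein variants sit below residue 4000, so an
#' ambiguous mention with position >= 4000 is classified \code{NSM}.
#'
#' @param mention one mention (a one-row data.frame or list with fields
#'   \code{kind} and \code{position_text}).
#' @return \code{"PSM"}, \code{"NSM"} or \code{"BOTH"}.
#' @examples
#' classifyLevel(list(kind = "AMBIGUOUS", position_text = "123"))   # BOTH
#' classifyLevel(list(kind = "AMBIGUOUS", position_text = "5123"))  # NSM
#' @export
classifyLevel <- function(mention) {
  kind <- as.character(mention$kind)
  if (kind == "PSM") return("PSM")
  if (kind == "NSM") return("NSM")
  if (kind != "AMBIGUOUS")
    stop("classifyLevel expects a PSM/NSM/AMBIGUOUS mention")
  pos <- suppressWarnings(as.integer(mention$position_text))
  if (!is.na(pos) && pos >= 4000L) "NSM" else "BOTH"
}

#' Associate separately tagged sub-entities into variant tuples
#'
#' Taggers that label alleles and locations as separate fragments need the
#' fragments combined into (wild type, location, mutated) triples. Two
#' allele fragments joined only by substitution-arrow characters (as in
#' \code{"C>G"}) form one intact allele unit and attach to the nearest
#' location, tolerating a listing comma as in \code{"(-19, C>G)"}. An
#' isolated location is otherwise paired with its nearest preceding and
#' nearest following allele fragment, and such a pairing is vetoed when a
#' delimiting character (comma, period, semicolon, bracket) or a sentence
#' boundary lies between the two fragments; this prevents e.g. pairing an
#' allele with a location across \code{"...G, 261..."}. Locations without
#' both alleles are dropped.
#'
#' @param fragments data.frame with columns \code{start}, \code{end}
#'   (0-based half-open offsets) and \code{role} (\code{"location"} or
#'   \code{"allele"}).
#' @param text the document text the offsets refer to.
#' @param doc_id document identifier for the standoff output.
#' @return standoff data.frame of assembled mentions (same columns as
#'   \code{\link{findMentions}}).
#' @export
associateSubentities <- function(fragments, text, doc_id = "doc1") {
  stopifnot(all(c("start", "end", "role") %in% names(fragments)))
  fragments$surface <- substring(text, fragments$start + 1L, fragments$end)
  locs <- fragments[fragments$role == "location", , drop = FALSE]
  alls <- fragments[fragments$role == "allele", , drop = FALSE]
  alls <- alls[order(alls$start), , drop = FALSE]
  vetoed <- function(a, b, soft_comma = FALSE) {
    lo <- min(a$end, b$end); hi <- max(a$start, b$start)
    if (hi <= lo) return(FALSE)
    gap <- substring(text, lo + 1L, hi)
    hard <- grepl("[][;.()]", gap) || grepl("\n", gap, fixed = TRUE) ||
      grepl(". ", gap, fixed = TRUE)
    if (soft_comma) hard else hard || grepl(",", gap, fixed = TRUE)
  }
  # arrow-joined allele fragments form one intact substitution unit
  unit_of <- seq_len(nrow(alls))
  if (nrow(alls) > 1L) for (i in seq_len(nrow(alls) - 1L)) {
    gap <- substring(text, alls$end[i] + 1L, alls$start[i + 1L])
    if (grepl("^[->=/ ]*$", gap) && unit_of[i + 1L] == i + 1L)
      unit_of[i + 1L] <- unit_of[i]
  }
  out <- list()
  used_alleles <- logical(nrow(alls))
  for (i in seq_len(nrow(locs))) {
    L <- locs[i, ]
    pre <- NULL; post <- NULL
    # complete two-allele unit nearest to the location, comma tolerated
    units <- split(seq_len(nrow(alls)), unit_of)
    pair_units <- Filter(function(ix) length(ix) == 2L &&
                           !any(used_alleles[ix]), units)
    if (length(pair_units)) {
      udist <- function(ix, loc) {
        u <- alls[ix, ]
        min(abs(c(u$start - loc$end, loc$start - u$end)))
      }
      dist <- vapply(pair_units, udist, numeric(1), loc = L)
      ix <- pair_units[[which.min(dist)]]
      # mutual nearest: another location closer to this unit keeps it
      other <- vapply(seq_len(nrow(locs)), function(j)
        udist(ix, locs[j, ]), numeric(1))
      if (min(dist) <= min(other)) {
        u1 <- alls[ix[1L], ]; u2 <- alls[ix[2L], ]
        span <- list(start = min(u1$start, u2$start),
                     end = max(u1$end, u2$end))
        if (!vetoed(L, span, soft_comma = TRUE)) {
          pre <- u1; post <- u2; used_alleles[ix] <- TRUE
        }
      }
    }
    if (is.null(pre)) {  # fall back to nearest flanking single alleles
      free <- alls[!used_alleles, , drop = FALSE]
      p <- free[free$end <= L$start, , drop = FALSE]
      q <- free[free$start >= L$end, , drop = FALSE]
      p <- p[order(-p$end), , drop = FALSE]
      q <- q[order(q$start), , drop = FALSE]
      pre <- if (nrow(p) && !vetoed(p[1, ], L)) p[1, ] else NULL
      post <- if (nrow(q) && !vetoed(L, q[1, ])) q[1, ] else NULL
    }
    if (is.null(pre) || is.null(post)) next
    w <- pre$surface; mu <- post$surface
    signed <- grepl("^-|[+-]\\d+$", L$surface)
    kind <- if (signed || !all(c(w, mu) %in% AA_ONE)) "NSM"
            else if (all(c(w, mu) %in% NUCLEOTIDES)) "AMBIGUOUS" else "PSM"
    row <- mentionRow(doc_id, 0L, 0L, kind = kind, wild = w, mutated = mu,
                      position_text = L$surface)
    row$start <- min(pre$start, L$start)
    row$end <- max(post$end, L$end)
    row$surface <- substring(text, row$start + 1L, row$end)
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) return(emptyMentions())
  df <- do.call(rbind, out)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df[, MENTION_COLUMNS]
}

#' Write mentions as standoff TSV
#'
#' @param mentions standoff data.frame from \code{\link{findMentions}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMentionsTsv <- function(mentions, path) {
  out <- mentions[, setdiff(MENTION_COLUMNS, "scheme_hint")]
  out$rs_number <- ifelse(is.na(out$rs_number), "",
                          format(out$rs_number, scientific = FALSE,
                                 trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
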