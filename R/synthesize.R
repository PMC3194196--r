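#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the documented structure of SNP-mention corpora:
#' documents that mention one gene and several of its variants, rendered
#' in a mixture of nomenclature conventions, with an optional rs-identifier
#' citation, and with controllable corruption reproducing the documented
#' systematic error classes (initiator-methionine offsets, Signal-feature
#' offsets, opposite-strand record storage, flipped directionality,
#' digit-permuted rs citations) plus an unmodeled constant offset that no
#' annotation explains.
#'
#' The protein share (0.54) and the notation mixture follow the observed
#' composition of published SNP mentions: protein-level descriptions
#' slightly outnumber nucleotide-level ones, unprefixed legacy forms
#' dominate the nucleotide-level mentions, and explicit
#' \code{c.}/\code{g.} prefixes and IVS forms are minorities.
#'
#' @param n_genes number of genes (= documents).
#' @param snps_per_gene variants planted per gene.
#' @param decoys_per_gene non-mentioned records per gene, drawn to avoid
#'   position/allele collisions with the document's mentions.
#' @param exons_per_gene,exon_length,intron_length integer ranges
#'   \code{c(min, max)}.
#' @param utr5_length,utr3_length transcript-coordinate UTR length ranges.
#' @param notation_mix named proportions over NSM schemes (must sum to 1).
#' @param psm_share fraction of mentions rendered at protein level.
#' @param rs_mention_share fraction of variants additionally cited by rs
#'   identifier.
#' @param corruption named probabilities for \code{init_met_offset},
#'   \code{signal_offset}, \code{strand_flip}, \code{direction_flip},
#'   \code{rs_typo}, \code{unmodeled_offset}.
#' @param seed integer seed; corpora are byte-identical given the same
#'   configuration.
#' @return a validated config list of class \code{snpground_synth_config}.
#' @export
synthConfig <- function(n_genes = 125L, snps_per_gene = 4L,
                        decoys_per_gene = 3L,
                        exons_per_gene = c(1L, 4L),
                        exon_length = c(120L, 600L),
                        intron_length = c(80L, 2000L),
                        utr5_length = c(30L, 200L),
                        utr3_length = c(30L, 200L),
                        notation_mix = c(LEGACY1993 = 0.40, GENOMIC = 0.20,
                                         IVS = 0.08, HGVS_C = 0.32),
                        psm_share = 0.54, rs_mention_share = 0.2,
                        corruption = c(init_met_offset = 0,
                                       signal_offset = 0, strand_flip = 0,
                                       direction_flip = 0, rs_typo = 0,
                                       unmodeled_offset = 0),
                        seed = 1L) {
  full <- c(init_met_offset = 0, signal_offset = 0, strand_flip = 0,
            direction_flip = 0, rs_typo = 0, unmodeled_offset = 0)
  full[names(corruption)] <- corruption
  stopifnot(abs(sum(notation_mix) - 1) < 1e-8,
            all(full >= 0 & full <= 1),
            psm_share >= 0, psm_share <= 1,
            all(names(notation_mix) %in% POSITION_SCHEMES))
  structure(list(n_genes = as.integer(n_genes),
                 snps_per_gene = as.integer(snps_per_gene),
                 decoys_per_gene = as.integer(decoys_per_gene),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 utr5_length = as.integer(utr5_length),
                 utr3_length = as.integer(utr3_length),
                 notation_mix = notation_mix, psm_share = psm_share,
                 rs_mention_share = rs_mention_share, corruption = full,
                 seed = as.integer(seed)),
            class = "snpground_synth_config")
}

rint <- function(range) if (range[1] >= range[2]) range[1] else
  sample(seq.int(range[1], range[2]), 1L)

randomGeneModel <- function(gene_id, cfg, base) {
  n_ex <- rint(cfg$exons_per_gene)
  widths <- vapply(seq_len(n_ex), function(i) rint(cfg$exon_length),
                   integer(1))
  L <- sum(widths)
  u5 <- rint(cfg$utr5_length); u3 <- rint(cfg$utr3_length)
  need <- u5 + u3 + 153L  # at least 51 codons
  if (L < need) { widths[n_ex] <- widths[n_ex] + (need - L); L <- need }
  gaps <- if (n_ex > 1L)
    vapply(seq_len(n_ex - 1L), function(i) rint(cfg$intron_length),
           integer(1)) else integer()
  starts <- base + cumsum(c(0L, widths[-n_ex] + gaps))
  ends <- starts + widths - 1L
  strand <- sample(c("+", "-"), 1L)
  cds_len <- 3L * ((L - u5 - u3) %/% 3L)
  # provisional model just to map transcript positions to the reference
  prov <- geneModel(gene_id, strand = strand, exons = cbind(starts, ends),
                    cds_start = if (strand == "+") starts[1L] else ends[n_ex],
                    cds_end = if (strand == "+") starts[1L] else ends[n_ex])
  geo <- modelGeometry(prov)
  refOf <- function(tp) geo$fromU(geo$uOfTpos(tp))
  model <- geneModel(gene_id, strand = strand, exons = cbind(starts, ends),
                     cds_start = refOf(u5 + 1L),
                     cds_end = refOf(u5 + cds_len))
  list(model = model, n_codons = cds_len %/% 3L, u5 = u5,
       transcript_length = L)
}

permuteDigits <- function(rs_id) {
  d <- strsplit(format(rs_id, scientific = FALSE), "")[[1]]
  idx <- which(d[-length(d)] != d[-1])
  if (!length(idx)) return(rs_id + 1)
  i <- if (length(idx) == 1L) idx else sample(idx, 1L)
  tmp <- d[i]; d[i] <- d[i + 1L]; d[i + 1L] <- tmp
  out <- as.numeric(paste(d, collapse = ""))
  if (substr(paste(d, collapse = ""), 1, 1) == "0") rs_id + 1 else out
}

# build a mention row without running recognition (used for collision
# rejection while drawing records)
synthMentionRow <- function(kind, wild, mutated, position_text,
                            scheme_hint = "") {
  mentionRow("synth", 0L, 0L, kind = kind, wild = wild,
             mutated = paste(mutated, collapse = ","),
             position_text = position_text, scheme_hint = scheme_hint)
}

mentionMatchesRecord <- function(mention, rec, store) {
  level <- classifyLevel(mention)
  if (level %in% c("PSM", "BOTH")) {
    ann <- annotationForGenes(store, rec@gene_ids)
    if (matchPsm(mention, rec, ann)@matched) return(TRUE)
  }
  if (level %in% c("NSM", "BOTH")) {
    if (matchNsm(mention, rec, modelsForGenes(store, rec@gene_ids))@matched)
      return(TRUE)
  }
  FALSE
}

#' Generate a synthetic corpus with gold annotations
#'
#' Builds random gene models, plants variant records on them, renders each
#' variant as a textual mention in a sampled notation (including arrow
#' dialects), assembles one document per gene, and applies the configured
#' corruption operations, recording each in the gold annotation's
#' \code{error_class}. Records are drawn by rejection so that every
#' mention of a document validates against exactly its generating record
#' (against none for unmodeled-offset corruptions), so at zero corruption
#' the end-to-end pipeline recovers every pair and invents none.
#'
#' @param cfg a configuration from \code{\link{synthConfig}}.
#' @return list with \code{documents} (named character vector),
#'   \code{gene_map} (doc_id to gene ids), \code{gold} (data.frame:
#'   \code{doc_id}, \code{start}, \code{end}, \code{surface},
#'   \code{rs_id}, \code{error_class}), \code{store} (a
#'   \linkS4class{SnpStore}) and \code{config}.
#' @examples
#' corpus <- generateSyntheticCorpus(synthConfig(n_genes = 3L, seed = 7L))
#' corpus$documents[[1]]
#' @export
generateSyntheticCorpus <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "snpground_synth_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(cfg$seed)
  pr <- cfg$corruption
  arrow_dialects <- c(">", "\u2192", "-->", "\u2013 \u2013>")
  tabs <- alphabetTables()
  all_records <- list(); all_models <- list(); all_annotations <- list()
  documents <- character(); gene_map <- list(); gold <- list()
  next_rs <- 5000000

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("SYNG%03d", g)
    doc_id <- sprintf("doc%03d", g)
    gm <- randomGeneModel(gene_id, cfg, base = 100000L * g)
    model <- gm$model
    geo <- modelGeometry(model)
    ann <- proteinAnnotation(sprintf("SYNP%03d", g), gene_id)
    gene_records <- list(); gene_mentions <- list()

    # every mention must validate against exactly its generating record
    # (against none when its offset is unmodeled)
    consistent <- function(records, mentions, ann) {
      st <- snpStore(records, list(model), list(ann))
      for (m in mentions) {
        for (r in records) {
          want <- identical(r@rs_id, m$rs_id) &&
            m$error_class != "unmodeled_offset"
          if (mentionMatchesRecord(m$row, r, st) != want) return(FALSE)
        }
      }
      TRUE
    }

    planted <- 0L; tries <- 0L
    while (planted < cfg$snps_per_gene && tries < 300L) {
      tries <- tries + 1L
      is_psm <- stats::runif(1) < cfg$psm_share
      unmodeled <- stats::runif(1) < pr[["unmodeled_offset"]]
      flip_dir <- stats::runif(1) < pr[["direction_flip"]]
      classes <- character()
      if (flip_dir) classes <- c(classes, "direction_flip")
      ann_new <- ann
      if (is_psm) {
        r <- rint(c(2L, gm$n_codons - 1L))
        res <- sample(setdiff(AA_ONE, "J"), 2L)
        rec_pos <- geo$fromU(geo$uOfTpos(gm$u5 + 3L * r - 1L))
        alle <- sample(NUCLEOTIDES, 2L)
        rec_rpos <- r
        if (stats::runif(1) < pr[["init_met_offset"]]) {
          classes <- c(classes, "init_met_offset")
          rec_rpos <- r + 1L
          ann_new@initiator_met_cleaved <- TRUE
        } else if (stats::runif(1) < pr[["signal_offset"]]) {
          classes <- c(classes, "signal_offset")
          have <- ann_new@features
          prev <- have[have$kind == "Signal", , drop = FALSE]
          sig <- if (nrow(prev)) prev$end[1L] else rint(c(10L, 40L))
          if (!nrow(prev))
            ann_new@features <- rbind(have, data.frame(
              kind = "Signal", begin = 1L, end = sig,
              stringsAsFactors = FALSE))
          rec_rpos <- r + sig
        }
        mention_pos <- if (unmodeled) r + 52L else r
        mres <- if (flip_dir) rev(res) else res
        one_letter <- stats::runif(1) < 0.5
        three <- names(AA_THREE_TO_ONE)
        surface <- if (one_letter)
          sprintf("%s%d%s", mres[1], mention_pos, mres[2])
        else sprintf("%s%d%s", three[match(mres[1], AA_THREE_TO_ONE)],
                     mention_pos, three[match(mres[2], AA_THREE_TO_ONE)])
        if (one_letter && surface %in% tabs$stoplist) next
        kind <- if (one_letter && all(mres %in% NUCLEOTIDES)) "AMBIGUOUS"
                else "PSM"
        mrow <- synthMentionRow(kind, mres[1], mres[2],
                                as.character(mention_pos))
        rec <- snpRecord(next_rs, gene_id, rec_pos, alle,
                         reference = model@reference,
                         residue_position = rec_rpos, residues = res)
      } else {
        scheme <- sample(names(cfg$notation_mix), 1L,
                         prob = cfg$notation_mix)
        if (scheme == "IVS" && geo$n_exon < 2L) scheme <- "HGVS_C"
        if (scheme == "IVS") {
          i <- rint(c(1L, geo$n_exon - 1L))
          gaplen <- geo$us[i + 1L] - geo$ue[i] - 1L
          d <- rint(c(1L, min(gaplen, 60L)))
          u <- if (stats::runif(1) < 0.5) geo$ue[i] + d else
            geo$us[i + 1L] - d
          gpos <- geo$fromU(u)
        } else {
          tp <- rint(c(1L, gm$transcript_length))
          gpos <- geo$fromU(geo$uOfTpos(tp))
        }
        expr <- tryCatch(renderPosition(model, gpos, scheme),
                         error = function(e) NULL)
        if (is.null(expr)) next
        ptxt <- formatPosition(expr, prefix = FALSE)
        if (unmodeled) {
          if (expr@offset != 0L || expr@star) next  # shift plain anchors only
          shifted <- expr@anchor + 52L
          if (shifted == 0L) next
          ptxt <- as.character(shifted)
        }
        hint <- if (scheme == "HGVS_C") "c."
          else if (scheme == "GENOMIC" && stats::runif(1) < 0.5) "g."
          else ""
        alle <- sample(NUCLEOTIDES, 2L)
        wild <- alle[1L]; mut <- alle[2L]
        if (flip_dir) { wild <- alle[2L]; mut <- alle[1L] }
        orientation <- "same"; stored <- alle
        if (stats::runif(1) < pr[["strand_flip"]]) {
          classes <- c(classes, "strand_flip")
          orientation <- "opposite"; stored <- complementAlleles(alle)
        }
        surface <- paste0(hint, ptxt, wild, sample(arrow_dialects, 1L),
                          mut)
        mrow <- synthMentionRow("NSM", wild, mut, ptxt, hint)
        rec <- snpRecord(next_rs, gene_id, gpos, stored,
                         orientation = orientation,
                         reference = model@reference)
      }
      if (unmodeled) classes <- "unmodeled_offset"
      error_class <- if (length(classes)) paste(classes, collapse = "+")
                     else "none"
      if (surface %in% vapply(gene_mentions, function(m) m$surface,
                              character(1))) next
      cand <- list(surface = surface, row = mrow, rs_id = rec@rs_id,
                   error_class = error_class,
                   cite_rs = stats::runif(1) < cfg$rs_mention_share,
                   rs_typo = FALSE, wrong_rs = NA_real_)
      cand$rs_typo <- cand$cite_rs && stats::runif(1) < pr[["rs_typo"]]
      if (!consistent(c(gene_records, list(rec)),
                      c(gene_mentions, list(cand)), ann_new)) next
      ann <- ann_new
      gene_records[[length(gene_records) + 1L]] <- rec
      gene_mentions[[length(gene_mentions) + 1L]] <- cand
      next_rs <- next_rs + 1
      planted <- planted + 1L
    }

    # rs-typo decoys: the permuted id exists in the store but encodes a
    # different variant, so the citation can be flagged inconsistent
    for (mi in seq_along(gene_mentions)) {
      m <- gene_mentions[[mi]]
      if (!m$rs_typo) next
      existing <- vapply(c(all_records, gene_records), rsId, numeric(1))
      wrong <- permuteDigits(m$rs_id)
      guard <- 0L
      while (wrong %in% existing && guard < 20L) {
        wrong <- permuteDigits(wrong); guard <- guard + 1L
      }
      for (k in seq_len(100L)) {
        pos <- rint(c(100000L * g + 90000L, 100000L * g + 95000L))
        dec <- snpRecord(wrong, gene_id, pos, sample(NUCLEOTIDES, 2L),
                         reference = model@reference)
        st <- snpStore(c(gene_records, list(dec)), list(model), list(ann))
        clash <- any(vapply(gene_mentions, function(mm)
          mentionMatchesRecord(mm$row, dec, st), logical(1)))
        if (!clash) { gene_records[[length(gene_records) + 1L]] <- dec
                      break }
      }
      gene_mentions[[mi]]$wrong_rs <- wrong
    }

    # plain decoys, rejected against every mention of the document
    for (k in seq_len(cfg$decoys_per_gene)) {
      for (t in seq_len(100L)) {
        tp <- rint(c(1L, gm$transcript_length))
        dec <- snpRecord(next_rs, gene_id, geo$fromU(geo$uOfTpos(tp)),
                         sample(NUCLEOTIDES, 2L),
                         reference = model@reference)
        st <- snpStore(c(gene_records, list(dec)), list(model), list(ann))
        clash <- any(vapply(gene_mentions, function(mm)
          mentionMatchesRecord(mm$row, dec, st), logical(1)))
        if (!clash) { gene_records[[length(gene_records) + 1L]] <- dec
                      next_rs <- next_rs + 1; break }
      }
    }

    # assemble the document, tracking mention spans (0-based half-open)
    text <- sprintf("Gene %s polymorphism study.", model@symbol)
    for (m in gene_mentions) {
      pre <- " We observed the "
      start <- nchar(text) + nchar(pre)
      text <- paste0(text, pre, m$surface, " variant.")
      gold[[length(gold) + 1L]] <- data.frame(
        doc_id = doc_id, start = start, end = start + nchar(m$surface),
        surface = m$surface, rs_id = m$rs_id, error_class = m$error_class,
        stringsAsFactors = FALSE)
      if (m$cite_rs) {
        cited <- if (m$rs_typo) m$wrong_rs else m$rs_id
        rs_surface <- sprintf("rs%s", format(cited, scientific = FALSE))
        pre2 <- " This variant is listed as "
        start2 <- nchar(text) + nchar(pre2)
        text <- paste0(text, pre2, rs_surface, ".")
        gold[[length(gold) + 1L]] <- data.frame(
          doc_id = doc_id, start = start2,
          end = start2 + nchar(rs_surface), surface = rs_surface,
          rs_id = m$rs_id,
          error_class = if (m$rs_typo) "rs_typo" else "rs_direct",
          stringsAsFactors = FALSE)
      }
    }
    documents[[doc_id]] <- text
    gene_map[[doc_id]] <- gene_id
    all_records <- c(all_records, gene_records)
    all_models <- c(all_models, list(model))
    all_annotations <- c(all_annotations, list(ann))
  }
  list(documents = documents, gene_map = gene_map,
       gold = do.call(rbind, gold),
       store = snpStore(all_records, all_models, all_annotations),
       config = cfg)
}
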