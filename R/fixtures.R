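#' MECP2-like worked-example gene model and records
#'
#' A plus-strand gene model reconstructed so that its two example SNPs
#' reproduce all four nomenclature conventions exactly: the 5'UTR SNP at
#' reference position 4943 renders as \code{2} (cap-based transcript
#' numbering), \code{4943} (genomic), \code{-225} (IVS convention, counted
#' from the A of the start codon) and \code{c.-225} (HGVS coding
#' numbering), and the intronic SNP at 10490 as \code{252+2},
#' \code{10490}, \code{IVS2+2} and \code{c.26+2}. Exon boundaries are
#' consistency-derived from those eight representations (transcript
#' position 252 at the exon-2 end, c.1 at transcript position 227); the
#' records carry synthetic rs identifiers.
#'
#' @return list with \code{model} (a \linkS4class{GeneModel}),
#'   \code{records} (two \linkS4class{SnpRecord}s) and \code{store}
#'   (a \linkS4class{SnpStore} bundling them).
#' @examples
#' fx <- mecp2Fixture()
#' formatPosition(renderPosition(fx$model, 4943, "IVS"))  # "-225"
#' @export
mecp2Fixture <- function() {
  model <- geneModel(
    gene_id = "MECP2", symbol = "MECP2", reference = "NG_007107.1",
    strand = "+",
    exons = list(c(4942L, 5178L), c(10474L, 10488L), c(11200L, 11400L)),
    cds_start = 5168L, cds_end = 11350L, tss = 4942L)
  records <- list(
    snpRecord(9000001, "MECP2", 4943, c("C", "A"),
              reference = "NG_007107.1"),
    snpRecord(9000002, "MECP2", 10490, c("T", "C"),
              reference = "NG_007107.1"))
  list(model = model, records = records,
       store = snpStore(records, list(model)))
}

#' eNOS workflow fixture
#'
#' A fixture store for the worked normalization example: an eNOS/NOS3-like
#' gene whose coding position 894 carries a G/T variant encoding the
#' Glu298Asp substitution, plus decoy records at other positions. The
#' three co-referent mentions \code{Glu(298)>Asp}, \code{E298D} and
#' \code{894G>T} all normalize to the same (synthetic) identifier, which
#' mirrors rs1799983.
#'
#' @return list with \code{store} (a \linkS4class{SnpStore}),
#'   \code{gene_id} and \code{rs_id} of the true record.
#' @export
nos3Fixture <- function() {
  # 100 nt 5'UTR, CDS c.1..1503 (501 codons), codon 298 = c.892-894
  model <- geneModel("NOS3", symbol = "NOS3", reference = "SYN_NOS3.1",
                     strand = "+", exons = list(c(1001L, 7000L)),
                     cds_start = 1101L, cds_end = 2603L)
  true_rs <- 1799983
  records <- list(
    snpRecord(true_rs, "NOS3", 1994, c("G", "T"),
              reference = "SYN_NOS3.1", residue_position = 298,
              residues = c("E", "D")),
    snpRecord(9100001, "NOS3", 2200, c("A", "C"),
              reference = "SYN_NOS3.1"),
    snpRecord(9100002, "NOS3", 2500, c("C", "G"),
              reference = "SYN_NOS3.1", residue_position = 467,
              residues = c("P", "R")),
    snpRecord(9100003, "NOS3", 3100, c("A", "G"),
              reference = "SYN_NOS3.1"))
  list(store = snpStore(records, list(model)), gene_id = "NOS3",
       rs_id = true_rs)
}

#' Error-class table fixtures
#'
#' Loads the packaged fixture store and one-line documents reproducing the
#' documented systematic error classes: initiator-methionine +1 offsets,
#' mature-protein Signal-feature offsets, opposite-strand allele storage,
#' digit-permuted rs citations, duplicate co-located records and flipped
#' wild/mutated directionality. Gene models, record positions and alleles
#' are synthetic reconstructions chosen so each documented mention/record
#' relation holds; rs identifiers are the published ones.
#'
#' @return list with \code{store} (a \linkS4class{SnpStore}) and
#'   \code{documents} (data.frame with columns \code{doc_id}, \code{text},
#'   \code{gene_ids}, \code{surface}, \code{expected_rs},
#'   \code{expected_status}, \code{error_class}, \code{cited_rs}).
#' @export
tableFixtures <- function() {
  store_path <- system.file("extdata", "table_fixtures.json",
                            package = "snpground")
  docs_path <- system.file("extdata", "table_documents.tsv",
                           package = "snpground")
  store <- loadStore(store_path)
  documents <- utils::read.table(docs_path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE, na.strings = "",
                                 quote = "", comment.char = "")
  list(store = store, documents = documents)
}

# builder for the shipped fixture files; kept here so the files can be
# regenerated (not exported)
buildTableFixtures <- function() {
  recs <- list(); mods <- list(); anns <- list(); docs <- list()
  addDoc <- function(doc_id, text, gene_ids, surface, expected_rs,
                     expected_status, error_class, cited_rs = NA) {
    docs[[length(docs) + 1L]] <<- data.frame(
      doc_id = doc_id, text = text, gene_ids = gene_ids, surface = surface,
      expected_rs = expected_rs, expected_status = expected_status,
      error_class = error_class, cited_rs = cited_rs,
      stringsAsFactors = FALSE)
  }
  # single-exon helper: 100 nt 5'UTR, CDS of cds_len, transcript 6000 nt
  mono <- function(gene, base, cds_len = 1500L, exon_len = 6000L) {
    geneModel(gene, symbol = gene, reference = paste0("SYN_", gene, ".1"),
              strand = "+", exons = list(c(base, base + exon_len - 1L)),
              cds_start = base + 100L, cds_end = base + 100L + cds_len - 1L)
  }
  cpos <- function(base, n) base + 100L + n - 1L  # reference pos of c.n

  ## initiator-methionine offsets (+1)
  recs <- c(recs, list(
    snpRecord(605059, "HSD17B1", 1000, c("A", "G"),
              residue_position = 313, residues = c("S", "G")),
    snpRecord(5985, "F13A1", 1100, c("G", "T"),
              residue_position = 35, residues = c("V", "L"))))
  anns <- c(anns, list(
    proteinAnnotation("P14061", "HSD17B1", initiator_met_cleaved = TRUE),
    proteinAnnotation("P00488", "F13A1", initiator_met_cleaved = TRUE)))
  addDoc("initmet.1", "The Ser312Gly polymorphism was genotyped.", "HSD17B1",
         "Ser312Gly", 605059, "UNIQUE", "init_met")
  addDoc("initmet.2", "Carriers of the Val34Leu polymorphism were compared.",
         "F13A1", "Val34Leu", 5985, "UNIQUE", "init_met")
  addDoc("initmet.3", "The Val34Leu variant was analyzed.", "F13A1",
         "Val34Leu", 5985, "UNIQUE", "init_met")

  ## mature-protein Signal-feature offsets
  sigRow <- function(doc, mention, gene, rs, protein, sig_len, mat_pos,
                     residues) {
    recs <<- c(recs, list(
      snpRecord(rs, gene, 1200 + rs %% 997, c("C", "T"),
                residue_position = mat_pos + sig_len, residues = residues)))
    anns <<- c(anns, list(
      proteinAnnotation(protein, gene, features = data.frame(
        kind = "Signal", begin = 1L, end = sig_len))))
    addDoc(doc, sprintf("The %s polymorphism was studied.", mention), gene,
           mention, rs, "UNIQUE", "signal_feature")
  }
  sigRow("mature.1", "Val7Met", "NPPA", 5063, "P01160", 25L, 7L, c("V", "M"))
  sigRow("mature.2", "I405V", "CETP", 5882, "P11597", 17L, 405L, c("I", "V"))
  sigRow("mature.3", "Thr26Asn", "LTA", 1041981, "P01374", 34L, 26L,
         c("T", "N"))
  sigRow("mature.4", "Arg80Gly", "C3", 2230199, "P01024", 22L, 80L,
         c("R", "G"))
  sigRow("mature.5", "Thr715Pro", "SELP", 6136, "P16109", 41L, 715L,
         c("T", "P"))

  ## opposite-strand allele storage
  oppRow <- function(doc, mention, gene, base, rs, cn, rec_alleles) {
    mods <<- c(mods, list(mono(gene, base,
                               cds_len = if (cn > 1400L) 4200L else 1500L)))
    recs <<- c(recs, list(
      snpRecord(rs, gene, cpos(base, cn), rec_alleles,
                orientation = "opposite")))
    addDoc(doc, sprintf("The %s polymorphism was investigated.", mention),
           gene, mention, rs, "UNIQUE", "opposite_strand")
  }
  oppRow("strand.1", "T30C", "ESR1", 10000L, 2077647, 30L, c("A", "G"))
  # HGVS/IVS -135: 34 bases upstream of the cap with a 100 nt 5'UTR
  mods <- c(mods, list(mono("LTC4S", 20000L)))
  recs <- c(recs, list(snpRecord(1867561, "LTC4S", 19965, c("C", "G"),
                                 orientation = "opposite")))
  addDoc("strand.2", "The -135C>G polymorphism was investigated.", "LTC4S",
         "-135C>G", 1867561, "UNIQUE", "opposite_strand")
  oppRow("strand.3", "59G>A", "GSTP1", 30000L, 1572983, 59L, c("C", "T"))
  oppRow("strand.4", "G1287A", "SLC6A2", 40000L, 5569, 1287L, c("C", "T"))
  addDoc("strand.5", "The G1287A polymorphism was replicated.", "SLC6A2",
         "G1287A", 5569, "UNIQUE", "opposite_strand")
  oppRow("strand.6", "C699T", "CBS", 50000L, 234706, 699L, c("A", "G"))
  oppRow("strand.7", "3823G>A", "CYP19A1", 60000L, 4614723, 3823L,
         c("C", "T"))

  ## digit-permuted rs citations: the cited record exists but encodes a
  ## different variant; a sibling record validates the description
  typoPsm <- function(doc, mention, gene, wrong_rs, right_rs, pos,
                      residues) {
    recs <<- c(recs, list(
      snpRecord(right_rs, gene, 4000 + right_rs %% 997, c("G", "T"),
                residue_position = pos, residues = residues),
      snpRecord(wrong_rs, gene, 5000 + wrong_rs %% 997, c("C", "T"),
                residue_position = pos + 500L, residues = c("T", "M"))))
    addDoc(doc, sprintf("The %s variant (rs%d) was associated.", mention,
                        wrong_rs),
           gene, mention, right_rs, "UNIQUE", "rs_typo", wrong_rs)
  }
  typoPsm("rstypo.1", "V660L", "PGR", 1042638, 1042838, 660L, c("V", "L"))
  mods <- c(mods, list(mono("MTHFR", 70000L, cds_len = 2000L)))
  recs <- c(recs, list(
    snpRecord(2274967, "MTHFR", cpos(70000L, 1793L), c("G", "A")),
    snpRecord(2274976, "MTHFR", 73000, c("C", "T"))))
  addDoc("rstypo.2", "The 1793G>A variant (rs2274976) was associated.",
         "MTHFR", "1793G>A", 2274967, "UNIQUE", "rs_typo", 2274976)
  typoPsm("rstypo.3", "G482S", "PPARGC1A", 8192673, 8192678, 482L,
          c("G", "S"))
  typoPsm("rstypo.4", "T241M", "XRCC3", 861529, 861539, 241L, c("T", "M"))
  typoPsm("rstypo.5", "K178R", "MGMT", 2308237, 2308327, 178L, c("K", "R"))

  ## duplicate (unmerged, co-located) records
  mods <- c(mods, list(mono("ALOX5AP", 80000L)))
  recs <- c(recs, list(
    snpRecord(11553656, "ALOX5AP", cpos(80000L, -77L) + 1L, c("T", "C")),
    snpRecord(3213245, "ALOX5AP", cpos(80000L, -77L) + 1L, c("T", "C"))))
  addDoc("dup.1", "The -77T>C promoter polymorphism was typed.", "ALOX5AP",
         "-77T>C", 11553656, "AMBIGUOUS_DUPLICATE", "duplicate")
  mods <- c(mods, list(geneModel("ATP6", symbol = "ATP6",
                                 reference = "SYN_ATP6.1", strand = "+",
                                 exons = list(c(8500L, 8900L)),
                                 cds_start = 8600L, cds_end = 8850L)))
  recs <- c(recs, list(
    snpRecord(45566835, "ATP6", 8618, c("A", "T")),
    snpRecord(6670, "ATP6", 8618, c("A", "T"))))
  addDoc("dup.2", "The mitochondrial A8618T variant was observed.", "ATP6",
         "A8618T", 45566835, "AMBIGUOUS_DUPLICATE", "duplicate")

  ## flipped wild-type/mutated directionality
  mods <- c(mods, list(geneModel("CYP7A1", symbol = "CYP7A1",
                                 reference = "SYN_CYP7A1.1", strand = "+",
                                 exons = list(c(1001L, 1200L),
                                              c(2001L, 2200L),
                                              c(3001L, 3200L),
                                              c(5001L, 5400L)),
                                 cds_start = 1101L, cds_end = 5200L)))
  recs <- c(recs, list(snpRecord(2486001, "CYP7A1", 3611, c("T", "C"))))
  addDoc("flip.1", "The IVS3+411C>T polymorphism was studied.", "CYP7A1",
         "IVS3+411C>T", 2486001, "UNIQUE", "direction_flip")
  recs <- c(recs, list(
    snpRecord(2293275, "LEPR", 6100, c("G", "A"),
              residue_position = 312, residues = c("N", "S"))))
  addDoc("flip.2", "The S312N substitution was typed.", "LEPR", "S312N",
         2293275, "UNIQUE", "direction_flip")
  recs <- c(recs, list(
    snpRecord(1056836, "CYP1B1", 6200, c("C", "G"),
              residue_position = 432, residues = c("L", "V"))))
  addDoc("flip.3", "The p.V432L substitution was typed.", "CYP1B1",
         "p.V432L", 1056836, "UNIQUE", "direction_flip")

  list(store = snpStore(recs, mods, anns),
       documents = do.call(rbind, docs))
}
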