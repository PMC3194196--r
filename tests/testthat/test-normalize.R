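test_that("candidate retrieval pools records over the document's genes", {
  fx <- nos3Fixture()
  expect_length(candidateRecords(character(), fx$store), 0L)
  cands <- candidateRecords("NOS3", fx$store)
  expect_length(cands, 4L)
  ids <- vapply(cands, rsId, numeric(1))
  expect_equal(ids, sort(ids))   # deterministic rs order
  expect_length(candidateRecords("NO_SUCH_GENE", fx$store), 0L)
})

test_that("the co-referent eNOS mentions all ground to one identifier", {
  fx <- nos3Fixture()
  txt <- paste0("The Glu(298)– –>Asp (E298D; 894G– –>T) polymorphism of ",
                "eNOS (endothelial nitric oxide synthase) has been ",
                "related with cardiovascular disease.")
  out <- normalizeDocument(txt, fx$gene_id, fx$store)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$status == "UNIQUE"))
  expect_true(all(out$rs_ids == format(fx$rs_id, scientific = FALSE)))
})

test_that("co-located duplicate records are flagged with both identifiers", {
  model <- geneModel("ALOX5AP", exons = list(c(3001L, 8000L)),
                     cds_start = 3301L, cds_end = 7500L)
  pos <- resolvePosition(model, "-77", "HGVS_C")
  recs <- list(snpRecord(11553656, "ALOX5AP", pos, c("T", "C")),
               snpRecord(3213245, "ALOX5AP", pos, c("T", "C")))
  store <- snpStore(recs, list(model))
  out <- normalizeDocument("The -77T>C polymorphism.", "ALOX5AP", store)
  expect_equal(out$status, "AMBIGUOUS_DUPLICATE")
  got <- sort(as.numeric(strsplit(out$rs_ids, ";")[[1]]))
  expect_equal(got, c(3213245, 11553656))
})

test_that("matches on different genes are reported as such", {
  m1 <- geneModel("GA", exons = list(c(1000L, 4999L)), cds_start = 1100L,
                  cds_end = 4000L)
  m2 <- geneModel("GB", exons = list(c(9000L, 12999L)), cds_start = 9100L,
                  cds_end = 12000L)
  # the bare mention 250A>G resolves on both genes' coding numbering
  r1 <- snpRecord(101, "GA", resolvePosition(m1, "250", "HGVS_C"),
                  c("A", "G"))
  r2 <- snpRecord(202, "GB", resolvePosition(m2, "250", "HGVS_C"),
                  c("A", "G"))
  store <- snpStore(list(r1, r2), list(m1, m2))
  out <- normalizeDocument("We typed 250A>G here.", c("GA", "GB"), store)
  expect_equal(out$status, "MULTIPLE_GENES")
})

test_that("unmatched and rs-direct mentions get the right status", {
  fx <- nos3Fixture()
  out <- normalizeDocument("An unrelated 9999C>T variant.", fx$gene_id,
                           fx$store)
  expect_equal(out$status, "NO_MATCH")
  expect_equal(out$rs_ids, "")
  out2 <- normalizeDocument("The polymorphism rs1799983 is known.",
                            fx$gene_id, fx$store)
  expect_equal(out2$status, "RS_DIRECT")
  out3 <- normalizeDocument("The polymorphism rs424242 is unknown.",
                            fx$gene_id, fx$store)
  expect_equal(out3$status, "NO_MATCH")
})

test_that("an ambiguous mention validating on one path reports that path", {
  fx <- nos3Fixture()
  # E298D has a protein reading only; 894G>T has a nucleotide reading only
  out <- normalizeDocument("The A123T decoy and 894G– –>T variant.",
                           fx$gene_id, fx$store)
  nsm <- out[out$surface == "894G– –>T", ]
  expect_match(nsm$explanation, "scheme=")
})

test_that("inconsistent rs citations are flagged with a suggestion", {
  rec_right <- snpRecord(1042838, "PGR", 2000, c("G", "T"),
                         residue_position = 660, residues = c("V", "L"))
  rec_wrong <- snpRecord(1042638, "PGR", 3000, c("C", "T"),
                         residue_position = 100, residues = c("T", "M"))
  store <- snpStore(list(rec_right, rec_wrong))
  out <- normalizeDocument("The V660L variant (rs1042638) was reported.",
                           "PGR", store)
  rs_row <- out[grepl("^rs", out$surface), ]
  expect_equal(rs_row$status, "RS_INCONSISTENT")
  expect_equal(rs_row$rs_ids, "1042838")
  # the variant mention itself still grounds to the correct record
  v_row <- out[out$surface == "V660L", ]
  expect_equal(v_row$status, "UNIQUE")
  expect_equal(v_row$rs_ids, "1042838")

  # a citation the description supports is consistent
  chk <- checkRsConsistency(mkMention("RS", rs_number = 1042838),
                            mkMention("PSM", "V", "L", "660"), "PGR", store)
  expect_equal(chk$status, "consistent")
  # a cited id absent from the store cannot be judged
  chk2 <- checkRsConsistency(mkMention("RS", rs_number = 999999999),
                             mkMention("PSM", "V", "L", "660"), "PGR",
                             store)
  expect_equal(chk2$status, "unknown")
})

test_that("normalization output round-trips through the TSV writer", {
  fx <- nos3Fixture()
  out <- normalizeDocument("The E298D variant.", fx$gene_id, fx$store)
  path <- tempfile(fileext = ".tsv")
  writeNormalizationTsv(out, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$surface, "E298D")
  expect_equal(back$status, "UNIQUE")
})
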