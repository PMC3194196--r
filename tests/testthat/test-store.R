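test_that("JSON stores round-trip exactly", {
  fx <- nos3Fixture()
  ann <- proteinAnnotation("P29474", "NOS3", initiator_met_cleaved = TRUE,
                           features = data.frame(kind = "Signal",
                                                 begin = 1L, end = 20L))
  store <- snpStore(fx$store@records, fx$store@models, list(ann))
  path <- tempfile(fileext = ".json")
  writeStore(store, path)
  back <- loadStore(path)
  expect_length(back@records, length(store@records))
  for (i in seq_along(store@records)) {
    a <- store@records[[i]]; b <- back@records[[i]]
    expect_equal(a@rs_id, b@rs_id)
    expect_equal(a@position, b@position)
    expect_equal(a@alleles, b@alleles)
    expect_equal(a@orientation, b@orientation)
    expect_equal(a@residue_position, b@residue_position)
    expect_equal(a@residues, b@residues)
  }
  m <- back@models[[1]]
  expect_equal(IRanges::start(exonRanges(m)),
               IRanges::start(exonRanges(store@models[[1]])))
  expect_equal(m@cds_start, store@models[[1]]@cds_start)
  a2 <- back@annotations[[1]]
  expect_true(a2@initiator_met_cleaved)
  expect_equal(a2@features$end, 20L)
  # a second write of the re-loaded store is byte-identical
  path2 <- tempfile(fileext = ".json")
  writeStore(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("empty and malformed stores are handled with clear errors", {
  path <- tempfile(fileext = ".json")
  writeStore(snpStore(), path)
  empty <- loadStore(path)
  expect_length(empty@records, 0L)

  bad <- tempfile(fileext = ".json")
  writeLines('{"schema_version":1,"records":[{"rs_id":5}]}', bad)
  expect_error(loadStore(bad), "record 1")
})

test_that("record and annotation TSVs round-trip", {
  recs <- list(
    snpRecord(5569, c("SLC6A2", "ALT"), 2386, c("C", "T"),
              orientation = "opposite"),
    snpRecord(5985, "F13A1", 500, c("G", "T"), residue_position = 35,
              residues = c("V", "L")))
  path <- tempfile(fileext = ".tsv")
  writeSnpRecordsTsv(recs, path)
  back <- readSnpRecordsTsv(path)
  expect_equal(back[[1]]@gene_ids, c("SLC6A2", "ALT"))
  expect_equal(back[[1]]@orientation, "opposite")
  expect_equal(back[[2]]@residues, c("V", "L"))

  apath <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tgene_id\tinit_met\tfeatures",
               "P01374\tLTA\t0\tSignal:1-34",
               "P68871\tHBB\t1\t"), apath)
  anns <- readProteinAnnotationsTsv(apath)
  expect_equal(anns[[1]]@features$end, 34L)
  expect_false(anns[[1]]@initiator_met_cleaved)
  expect_true(anns[[2]]@initiator_met_cleaved)
  expect_equal(nrow(anns[[2]]@features), 0L)
})

test_that("gene models round-trip through the flat TSV format", {
  fx <- mecp2Fixture()
  path <- tempfile(fileext = ".tsv")
  writeGeneModelsTsv(list(fx$model), path)
  back <- readGeneModelsTsv(path)[[1]]
  expect_equal(IRanges::start(exonRanges(back)),
               IRanges::start(exonRanges(fx$model)))
  expect_equal(IRanges::end(exonRanges(back)),
               IRanges::end(exonRanges(fx$model)))
  expect_equal(back@cds_start, fx$model@cds_start)
  expect_equal(back@tss, fx$model@tss)
  expect_equal(formatPosition(renderPosition(back, 10490, "HGVS_C")),
               "c.26+2")
})

test_that("gene models load from GFF3", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("NG_007107.1", "test", "gene", "4942", "11400", ".", "+", ".",
          "ID=MECP2", sep = "\t"),
    paste("NG_007107.1", "test", "mRNA", "4942", "11400", ".", "+", ".",
          "ID=MECP2-201;Parent=MECP2", sep = "\t"),
    paste("NG_007107.1", "test", "exon", "4942", "5178", ".", "+", ".",
          "Parent=MECP2-201", sep = "\t"),
    paste("NG_007107.1", "test", "exon", "10474", "10488", ".", "+", ".",
          "Parent=MECP2-201", sep = "\t"),
    paste("NG_007107.1", "test", "exon", "11200", "11400", ".", "+", ".",
          "Parent=MECP2-201", sep = "\t"),
    paste("NG_007107.1", "test", "CDS", "5168", "5178", ".", "+", "0",
          "Parent=MECP2-201", sep = "\t"),
    paste("NG_007107.1", "test", "CDS", "10474", "10488", ".", "+", "0",
          "Parent=MECP2-201", sep = "\t"),
    paste("NG_007107.1", "test", "CDS", "11200", "11350", ".", "+", "0",
          "Parent=MECP2-201", sep = "\t")), gff)
  models <- readGeneModelsGff3(gff)
  expect_length(models, 1L)
  m <- models[[1]]
  expect_equal(m@gene_id, "MECP2")
  expect_equal(m@cds_start, 5168L)
  expect_equal(m@cds_end, 11350L)
  expect_equal(formatPosition(renderPosition(m, 10490, "HGVS_C")), "c.26+2")
})
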