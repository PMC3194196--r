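fx <- mecp2Fixture()

test_that("the worked-example SNPs render in all four conventions", {
  expect_equal(formatPosition(renderPosition(fx$model, 4943, "LEGACY1993")),
               "2")
  expect_equal(formatPosition(renderPosition(fx$model, 10490, "LEGACY1993")),
               "252+2")
  expect_equal(formatPosition(renderPosition(fx$model, 4943, "GENOMIC"),
                              prefix = FALSE), "4943")
  expect_equal(formatPosition(renderPosition(fx$model, 10490, "GENOMIC"),
                              prefix = FALSE), "10490")
  expect_equal(formatPosition(renderPosition(fx$model, 4943, "IVS")), "-225")
  expect_equal(formatPosition(renderPosition(fx$model, 10490, "IVS")),
               "IVS2+2")
  expect_equal(formatPosition(renderPosition(fx$model, 4943, "HGVS_C")),
               "c.-225")
  expect_equal(formatPosition(renderPosition(fx$model, 10490, "HGVS_C")),
               "c.26+2")
  # anchors of the coordinate origins
  expect_equal(renderPosition(fx$model, fx$model@tss, "LEGACY1993")@anchor,
               1L)
  expect_equal(renderPosition(fx$model, fx$model@cds_start,
                              "HGVS_C")@anchor, 1L)
})

test_that("resolution inverts rendering and rejects malformed input", {
  expect_equal(resolvePosition(fx$model, "26+2", "HGVS_C"), 10490L)
  expect_equal(resolvePosition(fx$model, "2", "LEGACY1993"), 4943L)
  expect_equal(resolvePosition(fx$model, "IVS2+2", "IVS"), 10490L)
  expect_equal(resolvePosition(fx$model, "-225", "IVS"), 4943L)
  expect_error(parsePosition("0", "HGVS_C"), "zero")
  expect_error(parsePosition("banana", "HGVS_C"), "malformed")
  expect_error(resolvePosition(fx$model, "999+2", "LEGACY1993"),
               "exon-edge")
})

test_that("enumeration covers all conventions and re-resolves uniquely", {
  reps <- enumerateRepresentations(fx$model, 10490)
  txt <- vapply(reps, formatPosition, character(1), prefix = FALSE)
  expect_setequal(txt, c("252+2", "10490", "IVS2+2", "26+2"))
  for (r in reps)
    expect_true(10490L %in% resolvePosition(fx$model, r))
  # a CDS-internal position in a single-exon model has no intronic forms
  m1 <- geneModel("m1", exons = list(c(100L, 700L)), cds_start = 150L,
                  cds_end = 650L)
  reps1 <- enumerateRepresentations(m1, 300)
  expect_true(all(vapply(reps1, function(e) e@offset == 0L, logical(1))))
  # two transcripts with different layouts: union of representations,
  # each resolving back to the input position under some model
  m2 <- geneModel("m1", exons = list(c(100L, 400L), c(500L, 700L)),
                  cds_start = 150L, cds_end = 650L)
  reps2 <- enumerateRepresentations(list(m1, m2), 600)
  expect_gt(length(reps2), length(enumerateRepresentations(m1, 600)))
  for (r in reps2) {
    back <- c(tryCatch(resolvePosition(m1, r), error = function(e) integer()),
              tryCatch(resolvePosition(m2, r), error = function(e) integer()))
    expect_true(600L %in% back)
  }
  expect_length(enumerateRepresentations(list(), 300), 0L)
})

test_that("rendering agrees with a base-by-base enumeration oracle", {
  models <- list(
    fx$model,
    geneModel("p3", exons = list(c(50L, 120L), c(200L, 260L),
                                 c(400L, 520L)),
              cds_start = 80L, cds_end = 480L),
    geneModel("m3", strand = "-",
              exons = list(c(50L, 120L), c(200L, 260L), c(400L, 520L)),
              cds_start = 490L, cds_end = 90L))
  set.seed(77)
  for (model in models) {
    lo <- min(IRanges::start(exonRanges(model))) - 20L
    hi <- max(IRanges::end(exonRanges(model)))
    pts <- sample(seq.int(lo, hi), 250L)
    mismatches <- character()
    for (p in pts) {
      for (s in c("LEGACY1993", "GENOMIC", "IVS", "HGVS_C")) {
        got <- tryCatch(formatPosition(renderPosition(model, p, s),
                                       prefix = (s == "HGVS_C")),
                        error = function(e) NA_character_)
        want <- naiveRender(model, p, s)
        # downstream-of-transcript positions are unrepresentable: both fail
        if (is.na(want)) next
        if (!identical(got, want))
          mismatches <- c(mismatches,
                          sprintf("%s %s pos %d: %s vs %s", model@gene_id,
                                  s, p, got, want))
      }
    }
    expect_identical(mismatches, character(0))
  }
})

test_that("no transcript-based expression ever has anchor zero and -1/+1 are adjacent", {
  m <- geneModel("z", exons = list(c(100L, 400L)), cds_start = 150L,
                 cds_end = 350L)
  for (s in c("LEGACY1993", "IVS", "HGVS_C")) {
    anchors <- vapply(80:400, function(p) renderPosition(m, p, s)@anchor,
                      integer(1))
    expect_false(any(anchors == 0L, na.rm = TRUE))
    p_plus <- resolvePosition(m, "1", s)
    p_minus <- resolvePosition(m, "-1", s)
    expect_equal(p_plus - p_minus, 1L)
  }
})

test_that("minus-strand genes number antiparallel to the reference", {
  m <- geneModel("mg", strand = "-",
                 exons = list(c(100L, 260L), c(400L, 520L)),
                 cds_start = 500L, cds_end = 150L)
  # walking the 5' exon in transcript order yields strictly rising anchors
  anchors <- vapply(520:400, function(p)
    renderPosition(m, p, "LEGACY1993")@anchor, integer(1))
  expect_equal(anchors, seq_len(121L))
  # the cap is the gene-strand-first base (highest reference coordinate)
  expect_equal(renderPosition(m, 520, "LEGACY1993")@anchor, 1L)
  # upstream means higher reference coordinates on the minus strand
  expect_equal(renderPosition(m, 521, "LEGACY1993")@anchor, -1L)
  # intronic offsets count along the gene strand
  e <- renderPosition(m, 399, "LEGACY1993")  # 1 base 3' of exon-1 end
  expect_equal(e@offset, 1L)
  expect_equal(resolvePosition(m, e), 399L)
})

test_that("equidistant intronic positions anchor to the 5' exon with '+'", {
  m <- geneModel("tie", exons = list(c(100L, 199L), c(301L, 399L)),
                 cds_start = 120L, cds_end = 380L)
  # intron spans 200..300 (101 bases); 250 is equidistant from both edges
  e <- renderPosition(m, 250, "LEGACY1993")
  expect_true(e@offset > 0L)   # 5' exon, "+" offset at the tie
  expect_equal(e@anchor, 100L)
  expect_equal(e@offset, 51L)
  e2 <- renderPosition(m, 251, "LEGACY1993")
  expect_true(e2@offset < 0L)
})

test_that("allele complementation is a Watson-Crick involution", {
  expect_setequal(complementAlleles(c("A", "G")), c("T", "C"))
  expect_setequal(complementAlleles(c("G", "A")), c("C", "T"))
  sets <- list(c("A"), c("C", "T"), c("A", "C", "G", "T"))
  for (s in sets)
    expect_equal(complementAlleles(complementAlleles(s)), s)
  expect_error(complementAlleles(c("A", "X")), "non-nucleotide")
})

test_that("gene model validity catches inconsistent structures", {
  expect_error(geneModel("bad", exons = list(c(100L, 200L), c(150L, 300L)),
                         cds_start = 120L, cds_end = 180L), "overlap")
  expect_error(geneModel("bad2", exons = list(c(100L, 200L)),
                         cds_start = 300L, cds_end = 180L), "exonic")
})
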