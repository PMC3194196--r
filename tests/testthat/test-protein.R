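test_that("offset candidates cover the documented maturation mechanisms", {
  ann <- proteinAnnotation(features = data.frame(kind = "Signal",
                                                 begin = 1L, end = 34L))
  cand <- offsetCandidates(ann)
  expect_equal(cand$delta[1], 0L)          # weakest assumption first
  expect_true(34L %in% cand$delta)

  cand <- offsetCandidates(proteinAnnotation(initiator_met_cleaved = TRUE))
  expect_equal(cand$delta, c(0L, 1L))
  expect_equal(cand$provenance, c("NONE", "INIT_MET"))

  cand <- offsetCandidates(proteinAnnotation())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$provenance, "NONE")

  # internal features and whole-chain isoform markers generate no offset
  ann2 <- proteinAnnotation(features = data.frame(
    kind = c("Peptide", "Var_seq"), begin = c(10L, 1L), end = c(40L, 523L)))
  expect_equal(offsetCandidates(ann2)$delta, 0L)
})

test_that("reconciliation explains documented mature/precursor offsets", {
  init <- proteinAnnotation(initiator_met_cleaved = TRUE)
  r <- reconcilePsm(34, c("V", "L"), 35, c("V", "L"), init)
  expect_true(r@matched)
  expect_equal(r@offset_provenance, "INIT_MET")

  sig <- proteinAnnotation(features = data.frame(kind = "Signal",
                                                 begin = 1L, end = 34L))
  r <- reconcilePsm(26, c("T", "N"), 60, c("T", "N"), sig)
  expect_true(r@matched)
  expect_equal(r@offset_provenance, "FEATURE")
  expect_equal(r@offset_delta, 34L)

  # an unexplained constant offset stays unmatched
  r <- reconcilePsm(227, c("V", "I"), 279, c("V", "I"), proteinAnnotation())
  expect_false(r@matched)

  r <- reconcilePsm(298, c("E", "D"), 298, c("E", "D"), proteinAnnotation())
  expect_true(r@matched)
  expect_equal(r@offset_provenance, "NONE")

  # residue disagreement fails regardless of position
  r <- reconcilePsm(298, c("E", "D"), 298, c("E", "Q"), proteinAnnotation())
  expect_false(r@matched)
})

test_that("reconciliation is agnostic to wild/mutated direction", {
  set.seed(11)
  anns <- list(proteinAnnotation(),
               proteinAnnotation(initiator_met_cleaved = TRUE),
               proteinAnnotation(features = data.frame(
                 kind = "Signal", begin = 1L, end = 20L)))
  for (k in 1:50) {
    res <- sample(LETTERS[1:20], 2L)
    mpos <- sample(1:500, 1L)
    rpos <- mpos + sample(c(0L, 1L, 20L, 7L), 1L)
    ann <- anns[[sample(3L, 1L)]]
    a <- reconcilePsm(mpos, res, rpos, res, ann)
    b <- reconcilePsm(mpos, rev(res), rpos, res, ann)
    expect_equal(a@matched, b@matched)
  }
})

test_that("generating offsets are recovered with their provenance", {
  set.seed(12)
  for (k in 1:60) {
    r <- sample(10:400, 1L)
    res <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"), 2L)
    kind <- sample(c("none", "init", "signal"), 1L)
    if (kind == "none") {
      out <- reconcilePsm(r, res, r, res, proteinAnnotation())
      expect_equal(out@offset_provenance, "NONE")
    } else if (kind == "init") {
      ann <- proteinAnnotation(initiator_met_cleaved = TRUE)
      out <- reconcilePsm(r, res, r + 1L, res, ann)
      expect_equal(out@offset_provenance, "INIT_MET")
    } else {
      L <- sample(10:45, 1L)
      ann <- proteinAnnotation(features = data.frame(kind = "Signal",
                                                     begin = 1L, end = L))
      out <- reconcilePsm(r, res, r + L, res, ann)
      expect_equal(out@offset_provenance, "FEATURE")
      expect_equal(out@offset_delta, L)
    }
    expect_true(out@matched)
  }
})

test_that("adding features never removes a previously possible match", {
  base <- proteinAnnotation(initiator_met_cleaved = TRUE)
  richer <- proteinAnnotation(initiator_met_cleaved = TRUE,
                              features = data.frame(
                                kind = c("Signal", "Propeptide"),
                                begin = c(1L, 1L), end = c(18L, 25L)))
  for (d in c(0L, 1L, 18L, 25L)) {
    a <- reconcilePsm(100, c("V", "L"), 100 + d, c("V", "L"), base)
    b <- reconcilePsm(100, c("V", "L"), 100 + d, c("V", "L"), richer)
    if (a@matched) expect_true(b@matched)
  }
  # and the richer annotation explains what the base could not
  expect_true(reconcilePsm(100, c("V", "L"), 118, c("V", "L"),
                           richer)@matched)
})
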