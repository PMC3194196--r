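tabs <- alphabetTables()

test_that("protein-level mentions are detected in all documented forms", {
  m <- findProteinMentions("the Glu(298)>Asp substitution", tabs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$kind, "PSM")
  expect_equal(m$wild, "E"); expect_equal(m$mutated, "D")
  expect_equal(m$position_text, "298")

  m <- findProteinMentions("carrying A123T alleles", tabs)
  expect_equal(m$kind, "AMBIGUOUS")

  expect_equal(nrow(findProteinMentions("grown in T47D cells", tabs)), 0L)

  m <- findProteinMentions("the Ala357Thr mention", tabs)
  expect_equal(m$kind, "PSM")  # three-letter surface keeps the protein kind
  expect_equal(m$surface, "Ala357Thr")

  m <- findProteinMentions("a p.V432L substitution", tabs)
  expect_equal(m$kind, "PSM")
  expect_equal(m$surface, "p.V432L")

  m <- findProteinMentions("nonsense Trp26Ter and Gln39X variants", tabs)
  expect_equal(m$mutated, c("*", "*"))

  m <- findProteinMentions("ambiguous Xle405Val form", tabs)
  expect_equal(m$wild, "J")
})

test_that("nucleotide-level mentions preserve positions and alleles", {
  m <- findNucleotideMentions("found NM_005957.3:c.123G>T here", tabs)
  expect_equal(m$accession, "NM_005957.3")
  expect_equal(m$position_text, "123")
  expect_equal(m$scheme_hint, "c.")
  expect_equal(m$wild, "G"); expect_equal(m$mutated, "T")

  m <- findNucleotideMentions("the IVS3+411C>T variant", tabs)
  expect_equal(m$position_text, "IVS3+411")

  m <- findNucleotideMentions("alleles 82C>T/G were typed", tabs)
  expect_equal(m$mutated, "T,G")

  m <- findNucleotideMentions("promoter g.-420C>G variant", tabs)
  expect_equal(m$scheme_hint, "g.")
  expect_equal(m$position_text, "-420")

  m <- findNucleotideMentions("legacy -225C>A and 252+2T>C forms", tabs)
  expect_equal(m$position_text, c("-225", "252+2"))

  m <- findNucleotideMentions("allele-first G-2548A form", tabs)
  expect_equal(m$position_text, "-2548")
  expect_equal(m$kind, "NSM")
})

test_that("rs mentions obey the capitalization, keyword and blacklist rules", {
  m <- findRsMentions("the polymorphism rs1799983 was typed", tabs)
  expect_equal(m$rs_number, 1799983)

  expect_equal(nrow(findRsMentions("nothing in rs0 matches", tabs)), 0L)
  expect_equal(nrow(findRsMentions(
    "the polymorphism rs61443 is blacklisted", tabs)), 0L)
  # capitalized form without any trigger keyword in the document
  expect_equal(nrow(findRsMentions("an RS6000 computer", tabs)), 0L)
  # capitalized form with keyword present
  expect_equal(nrow(findRsMentions(
    "the SNP RS1799983 was reported", tabs)), 1L)
  # exclusion word vetoes capitalized matches even with a keyword
  expect_equal(nrow(findRsMentions(
    "a SNP in mouse strain RS1799983", tabs)), 0L)
  # lowercase matches are kept regardless of context
  expect_equal(nrow(findRsMentions("see rs1000234", tabs)), 1L)
})

test_that("overlapping candidates resolve longest-match-first", {
  m <- findMentions("found NM_005957.3:c.123G>T here", tabs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$surface, "NM_005957.3:c.123G>T")
  m <- findMentions("the c.26+2T>C site", tabs)
  expect_equal(m$surface, "c.26+2T>C")
})

test_that("sub-entity association pairs locations with flanking alleles", {
  # fragments as an upstream tagger would emit them
  t1 <- "promoter (-19, C>G) variant"
  fr1 <- data.frame(start = c(10L, 15L, 17L), end = c(13L, 16L, 18L),
                    role = c("location", "allele", "allele"))
  m <- associateSubentities(fr1, t1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$position_text, "-19")
  expect_equal(m$wild, "C"); expect_equal(m$mutated, "G")

  # two locations: the allele unit belongs to the nearer location, and the
  # comma vetoes re-pairing its trailing allele with the second location
  t2 <- "the -19 C>G change, near 261 a C was seen"
  off <- function(p) as.integer(regexpr(p, t2, fixed = TRUE)) - 1L
  fr2 <- data.frame(
    start = c(off("-19"), off("C>G"), off("C>G") + 2L, off("261"),
              off(" C w") + 1L),
    end = c(off("-19") + 3L, off("C>G") + 1L, off("C>G") + 3L,
            off("261") + 3L, off(" C w") + 2L),
    role = c("location", "allele", "allele", "location", "allele"))
  m <- associateSubentities(fr2, t2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$position_text, "-19")
  expect_equal(m$wild, "C"); expect_equal(m$mutated, "G")

  # a single allele without a location yields nothing
  fr3 <- data.frame(start = 0L, end = 1L, role = "allele")
  expect_equal(nrow(associateSubentities(fr3, "C here")), 0L)
})

test_that("sequence-level classification follows surface and position rules", {
  expect_equal(classifyLevel(mkMention("NSM", "T", "C", "26+2", "c.")),
               "NSM")
  expect_equal(classifyLevel(mkMention("AMBIGUOUS", "A", "T", "123")),
               "BOTH")
  # protein variants essentially never sit at residue >= 4000
  expect_equal(classifyLevel(mkMention("AMBIGUOUS", "A", "T", "5123")),
               "NSM")
  expect_equal(classifyLevel(mkMention("PSM", "E", "D", "298")), "PSM")
})

test_that("generator renderings are recovered with exact spans", {
  corpus <- generateSyntheticCorpus(synthConfig(n_genes = 8L, seed = 31L))
  for (d in names(corpus$documents)) {
    found <- findMentions(corpus$documents[[d]], tabs, doc_id = d)
    gold <- corpus$gold[corpus$gold$doc_id == d, ]
    for (i in seq_len(nrow(gold))) {
      hit <- found[found$start == gold$start[i] & found$end == gold$end[i], ]
      expect_equal(nrow(hit), 1L, info = gold$surface[i])
      expect_equal(hit$surface, gold$surface[i])
    }
    # no stoplisted or blacklisted surface is ever emitted
    expect_false(any(found$surface %in% tabs$stoplist))
  }
})
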