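# Generator determinism, ground truth, and background composition.

test_that("identical spec and seed give byte-identical outputs", {
  a <- generateCR("eremias_typical", seed = 9)
  b <- generateCR("eremias_typical", seed = 9)
  expect_identical(a$seq, b$seq)
  expect_identical(a$elements, b$elements)
  expect_identical(a$trs, b$trs)
  c_ <- generateCR("eremias_typical", seed = 10)
  expect_false(identical(a$seq, c_$seq))

  g1 <- generateMitogenome(seed = 5)
  g2 <- generateMitogenome(seed = 5)
  expect_identical(as.character(genomeSeq(g1$record)),
                   as.character(genomeSeq(g2$record)))
  expect_identical(mtFeatures(g1$record), mtFeatures(g2$record))

  s1 <- simulateCodonAlignment(3, 50, 0.1, 0.05, seed = 2)
  s2 <- simulateCodonAlignment(3, 50, 0.1, 0.05, seed = 2)
  expect_identical(as.character(s1$alignment), as.character(s2$alignment))
})

test_that("the annotation pipeline recovers every embedded element and
           repeat interval exactly", {
  for (preset in c("eremias_typical", "darevskia_typical",
                   "takydromus_typical", "minimal_V")) {
    for (seed in 1:3) {
      cr <- generateCR(preset, seed = seed)
      els <- annotateElements(cr$seq, restrictDownstream = FALSE)
      els <- els[order(els$start), ]
      expect_identical(els$element, cr$elements$element)
      expect_identical(els$start, cr$elements$start)
      expect_identical(els$end, cr$elements$end)
      expect_identical(els$matched_sequence, cr$elements$motif)
      trs <- findTandemRepeats(cr$seq)
      expect_identical(trs$start, cr$trs$start)
      expect_identical(trs$end, cr$trs$end)
      expect_identical(trs$period, cr$trs$period)
    }
  }
})

test_that("a spec without repeats produces a repeat-free CR", {
  cr <- generateCR("minimal_V", seed = 4)
  expect_equal(nrow(findTandemRepeats(cr$seq)), 0L)
  expect_equal(nrow(cr$trs), 0L)
})

test_that("an embedded TAS2 variant reports exactly its configured
           mismatch positions", {
  sp <- crPreset("darevskia_typical")   # TAS2 pattern T..G......
  cr <- generateCR(sp, seed = 6)
  hits <- fuzzyFind(cr$seq, "TAS2")
  best <- hits[hits$best, ]
  expect_equal(best$mismatch_positions, "1C>T;4A>G")
  expect_equal(best$dot_pattern, "T..G......")
})

test_that("shipped presets annotate back to their intended subtypes", {
  intended <- c(eremias_typical = "I-4", darevskia_typical = "II-1",
                takydromus_typical = "III-1", minimal_V = "V-1")
  for (preset in names(intended)) {
    cr <- generateCR(preset, seed = 8)
    els <- annotateElements(cr$seq, restrictDownstream = FALSE)
    trs <- findTandemRepeats(cr$seq)
    prof <- buildProfile(els, trs, nchar(cr$seq), preset)
    expect_equal(classifyCR(prof)$subtype, unname(intended[preset]),
                 info = preset)
  }
})

test_that("unrealizable specs are rejected", {
  sp <- crPreset("eremias_typical")
  sp$spacers["CSB2_CSB3"] <- -5
  expect_error(generateCR(sp, seed = 1), "unrealizable")
  sp2 <- crPreset("eremias_typical")
  sp2$elements$TAS2 <- "T..G....."   # wrong width
  expect_error(generateCR(sp2, seed = 1), "length")
})

test_that("background spacers track the requested AT content", {
  for (at in c(55, 65, 75)) {
    set.seed(123)
    s <- mitoCR:::.randomDNA(5000, at)
    cs <- computeComposition(s)
    expect_lt(abs(cs$at_percent - at), 2)
  }
})

test_that("generated genomes look like the study's records", {
  gm <- generateMitogenome(seed = 6)
  L <- length(genomeSeq(gm$record))
  expect_gte(L, 17000L); expect_lte(L, 21000L)
  ft <- mtFeatures(gm$record)
  expect_equal(sum(ft$type == "PCG"), 13L)
  expect_equal(sum(ft$type == "tRNA"), 22L)
  expect_equal(sum(ft$type == "rRNA"), 2L)
  expect_equal(ft$name[ft$strand == "L"],
               intersect(canonicalGeneOrder(), lightStrandGenes()))
  # H-strand PCGs carry valid starts/stops and no internal stops
  code <- Biostrings::getGeneticCode("2")
  s <- as.character(genomeSeq(gm$record))
  for (i in which(ft$type == "PCG")) {
    cds <- substr(s, ft$start[i] + 1L, ft$end[i])
    if (ft$strand[i] == "L")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    cods <- substring(cds, seq(1, nchar(cds) - 2, 3),
                      seq(3, nchar(cds), 3))
    expect_true(cods[1] %in% c("ATG", "GTG"), info = ft$name[i])
    expect_true(code[[cods[length(cods)]]] == "*", info = ft$name[i])
    expect_false(any(code[cods[-length(cods)]] == "*"), info = ft$name[i])
  }
  # exactly one O_L motif instance where configured
  ol <- scanOLMotif(gm$record)
  expect_equal(nrow(ol), 1L)
  expect_equal(ol$start, gm$truth$ol$start)
})
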