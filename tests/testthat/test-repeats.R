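# Tandem-repeat detection, positional classes, diagnostic motifs.

test_that("a perfect short repeat is reported with exact period and copies", {
  hits <- findTandemRepeats("ACGACGACGACG", minArrayLength = 12)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$period, 3L)
  expect_equal(hits$copy_number, 4)
  expect_equal(hits$mean_identity, 1)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 12L)
  expect_equal(hits$consensus, "ACG")
})

test_that("the Eremias repeat unit is detected with its consensus rotation", {
  # flanking bases are pinned so they cannot read as partial extra copies
  cr <- paste0(randomDNAString(99, seed = 31, at = 0.65), "C",
               strrep("TAGCGGCTTTTTTG", 3),
               "A", randomDNAString(99, seed = 32, at = 0.65))
  hits <- findTandemRepeats(cr)
  hit <- hits[hits$period == 14L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$copy_number, 3)
  expect_equal(hit$start, 100L)
  expect_equal(hit$end, 142L)
  doubled <- strrep(hit$consensus, 2)
  expect_true(grepl("TAGCGGCTTTTTTG", doubled, fixed = TRUE))
})

test_that("detector equals the exhaustive interval oracle on random strings", {
  for (seed in 1:6) {
    s <- randomDNAString(160, seed = 300 + seed, at = 0.65)
    # splice in a degenerate repeat for half the cases
    if (seed %% 2 == 0) {
      unit <- substr(s, 1, 6)
      arr <- strrep(unit, 5)
      substr(arr, 9, 9) <- "A"
      s <- paste0(substr(s, 1, 60), arr, substr(s, 61, 160))
    }
    got <- findTandemRepeats(s, minPeriod = 1, maxPeriod = 10)
    exp <- oracleTandemRepeats(s, minPeriod = 1, maxPeriod = 10)
    expect_equal(got, exp, info = paste("seed", seed))
  }
})

test_that("detector equals the oracle at larger scale and periods", {
  s <- paste0(randomDNAString(150, seed = 400, at = 0.65),
              strrep("CAAAACTTTTAA", 4),
              randomDNAString(150, seed = 401, at = 0.65))
  got <- findTandemRepeats(s, minPeriod = 1, maxPeriod = 20)
  exp <- oracleTandemRepeats(s, minPeriod = 1, maxPeriod = 20)
  expect_equal(got, exp)
})

test_that("raising the identity threshold never adds hits", {
  for (seed in c(7, 8)) {
    s <- paste0(randomDNAString(80, seed = seed),
                strrep("TTTTCC", 6), randomDNAString(80, seed = seed + 50))
    loose <- findTandemRepeats(s, minIdentity = 0.75)
    strict <- findTandemRepeats(s, minIdentity = 0.95)
    expect_lte(nrow(strict), nrow(loose))
  }
})

test_that("perfect repeats have period dividing the array length and a
           consensus equal to the unit up to rotation", {
  set.seed(17)
  for (i in 1:8) {
    p <- sample(3:12, 1)
    unit <- randomDNAString(p)
    copies <- sample(3:6, 1)
    # pin the flanking bases so they cannot read as partial extra copies
    pinL <- setdiff(c("A", "C", "G", "T"), substr(unit, p, p))[1]
    pinR <- setdiff(c("A", "C", "G", "T"), substr(unit, 1, 1))[1]
    s <- paste0(randomDNAString(49, at = 0.65), pinL, strrep(unit, copies),
                pinR, randomDNAString(49, at = 0.65))
    hits <- findTandemRepeats(s)
    hit <- hits[hits$start == 50L, ]
    if (nrow(hit) != 1L) next  # unit may be non-primitive; covered below
    expect_equal((hit$end - hit$start) %% hit$period, 0)
    expect_true(grepl(hit$consensus, strrep(unit, 2), fixed = TRUE))
  }
})

test_that("repeat positions classify against annotated elements", {
  cr <- generateCR("eremias_typical", seed = 1)
  els <- annotateElements(cr$seq, restrictDownstream = FALSE)
  trs <- findTandemRepeats(cr$seq)
  cls <- vapply(seq_len(nrow(trs)), function(i)
    classifyTrPosition(trs$start[i], trs$end[i], els)$position_class, "")
  expect_setequal(cls, c("before_TAS1", "after_CSB3"))
  norm <- vapply(seq_len(nrow(trs)), function(i)
    classifyTrPosition(trs$start[i], trs$end[i], els)$normality, "")
  expect_true(all(norm == "normal"))

  crD <- generateCR("darevskia_typical", seed = 2)
  elsD <- annotateElements(crD$seq, restrictDownstream = FALSE)
  trsD <- findTandemRepeats(crD$seq)
  clsD <- classifyTrPosition(trsD$start[1], trsD$end[1], elsD)
  expect_equal(clsD$position_class, "between_CSB1_CSB2")
  expect_equal(clsD$normality, "anormal")

  expect_equal(classifyTrPosition(10L, 40L, NULL)$position_class, "unplaced")
})

test_that("genus-diagnostic motifs are reported from repeat arrays", {
  cr <- generateCR("eremias_typical", seed = 3)
  rep1 <- genusMotifReport(findTandemRepeats(cr$seq), cr$seq)
  expect_true(rep1$present[rep1$motif == "TAGCGGCTTTTTTG"])

  crD <- generateCR("darevskia_typical", seed = 4)
  repD <- genusMotifReport(findTandemRepeats(crD$seq), crD$seq)
  expect_true(repD$present[repD$motif == "CAAAACTTTTAA"])

  empty <- genusMotifReport(findTandemRepeats("ACGT"), "ACGT")
  expect_false(any(empty$present))
})
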