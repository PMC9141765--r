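# Conserved-element fuzzy search, dot notation, variant tables.

test_that("an exact TAS2 occurrence is found with zero mismatches", {
  seq <- paste0(randomDNAString(80, seed = 1), "CATACATTAA",
                randomDNAString(80, seed = 2))
  hits <- fuzzyFind(seq, "TAS2")
  best <- hits[hits$best, ]
  expect_equal(best$start, 80L)
  expect_equal(best$mismatch_count, 0L)
  expect_equal(best$dot_pattern, "..........")
})

test_that("the updated TAS2 form reports mismatches at motif positions 1 and 4", {
  seq <- paste0(randomDNAString(60, seed = 3), "TATGCATTAA",
                randomDNAString(60, seed = 4))
  hits <- fuzzyFind(seq, "TAS2", maxMismatches = 2)
  best <- hits[hits$best, ]
  expect_equal(best$start, 60L)
  expect_equal(best$mismatch_count, 2L)
  expect_equal(best$mismatch_positions, "1C>T;4A>G")
  expect_equal(best$dot_pattern, "T..G......")
})

test_that("fuzzy search equals the exhaustive window oracle", {
  ref <- referenceMotifs()[["CSB1"]]
  for (seed in 1:5) {
    set.seed(seed)
    # embed a 3-mismatch CSB1 variant in a random 400 nt CR
    v <- strsplit(ref, "")[[1]]
    pos <- sample(nchar(ref), 3)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    cr <- paste0(randomDNAString(180), paste(v, collapse = ""),
                 randomDNAString(182))
    hits <- fuzzyFind(cr, "CSB1", maxMismatches = 9)
    oracle <- oracleWindowScan(cr, ref, 9)
    expect_setequal(hits$start, oracle$start)
    expect_equal(hits$mismatch_count[order(hits$start)],
                 oracle$mismatches[order(oracle$start)])
    best <- hits[hits$best, ]
    expect_equal(best$start, 180L)
    expect_equal(best$mismatch_count, 3L)
  }
  # generic property on short CRs for every element; TAS2 is searched with
  # both the classic and the updated anchor, so its oracle is the union
  for (el in names(referenceMotifs())) {
    cr <- randomDNAString(600, seed = 50 + match(el, names(referenceMotifs())),
                          at = 0.65)
    k <- defaultMaxMismatches()[[el]]
    hits <- fuzzyFind(cr, el, k)
    oracle <- oracleWindowScan(cr, referenceMotifs()[[el]], k)$start
    if (el == "TAS2")
      oracle <- union(oracle,
                      oracleWindowScan(cr, tas2Anchors()[["tas2_updated"]],
                                       k)$start)
    expect_setequal(hits$start, oracle)
  }
})

test_that("dot rendering and expansion are mutually inverse", {
  ref <- referenceMotifs()[["TAS2"]]
  expect_equal(renderDots(ref, ref), "..........")
  expect_equal(renderDots("TATGCATTAA", ref), "T..G......")
  expect_equal(expandDots("T..G......", ref), "TATGCATTAA")
  expect_error(renderDots("ACGT", ref), "length")
  set.seed(99)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), nchar(ref), replace = TRUE),
               collapse = "")
    expect_equal(expandDots(renderDots(x, ref), ref), x)
  }
})

test_that("the shipped TAS2 table parses with 26 types against a 10 nt
           reference and re-renders its own rows", {
  tb <- parseVariantTable("TAS2")
  expect_equal(nrow(tb$rows), 26L)
  expect_equal(nchar(tb$reference), 10L)
  expect_true(all(nchar(tb$rows$motif) == 10L))
  for (el in names(referenceMotifs())) {
    tb <- parseVariantTable(el)
    rerendered <- vapply(tb$rows$motif, renderDots, "",
                         reference = tb$reference, USE.NAMES = FALSE)
    expect_identical(rerendered, tb$rows$dot_pattern)
    expect_identical(vapply(strsplit(tb$rows$species, ";"), length, 0L),
                     tb$rows$n_species)
  }
})

test_that("a malformed variant-table row is rejected with its id", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("# element: TAS2", "# reference: CATACATTAA",
               "type_id\tn_species\tdot_pattern\tspecies",
               "1\t1\t..........\tSp. one",
               "2\t1\t...\tSp. two"), tmp)
  expect_error(parseVariantTable(tmp), "2")
})

test_that("variant typing is exact-match with novel fallback and is a
           partition over the shipped rows", {
  t5 <- parseVariantTable("CSB2")
  expect_equal(assignVariantType(referenceMotifs()[["CSB2"]], t5), "1")
  expect_equal(assignVariantType(strrep("A", 18), t5), "novel")
  for (el in names(referenceMotifs())) {
    tb <- parseVariantTable(el)
    got <- vapply(tb$rows$motif, assignVariantType, "", table = tb,
                  USE.NAMES = FALSE)
    expect_identical(got, as.character(tb$rows$type_id))
  }
})

test_that("taxa are counted by motif predicate, empty table counts zero", {
  t4 <- parseVariantTable("CSB1")
  expect_equal(tabulateVariantCounts(t4, function(m) m == t4$reference), 12L)
  empty <- t4; empty$rows <- t4$rows[0, ]
  expect_equal(tabulateVariantCounts(empty, function(m) TRUE), 0L)
})

test_that("element annotation restricts downstream searches and recovers
           generator layouts without restriction", {
  cr <- generateCR("darevskia_typical", seed = 5)
  for (restrict in c(TRUE, FALSE)) {
    found <- annotateElements(cr$seq, restrictDownstream = restrict)
    expect_equal(found$element[order(found$start)], cr$elements$element)
    expect_equal(found$start[order(found$start)], cr$elements$start)
  }
})
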