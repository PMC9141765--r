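# Gene-overlap scanning and O_L motif search.

test_that("the ATP8/ATP6 junction motif is found with length 10", {
  # two CDS joined through the conserved 10 nt overlap ATGGNNNTAA
  seq <- paste0(randomDNAString(60, seed = 1), "ATGGCCCTAA",
                randomDNAString(60, seed = 2))
  ft <- data.frame(name = c("ATP8", "ATP6"), strand = "H",
                   start = c(0L, 60L), end = c(70L, 130L),
                   wraps_origin = FALSE)
  rec <- Mitogenome("OV1", seq, ft)
  ov <- scanGeneOverlaps(rec)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlap_length, 10L)
  expect_equal(ov$overlap_sequence, "ATGGCCCTAA")
  expect_equal(ov$motif_class, "ATGGNNNTAA")
})

test_that("adjacent non-overlapping genes yield no overlap rows", {
  ft <- data.frame(name = c("ND1", "ND2"), strand = "H",
                   start = c(0L, 90L), end = c(90L, 180L),
                   wraps_origin = FALSE)
  rec <- Mitogenome("OV2", randomDNAString(200, seed = 3), ft)
  expect_equal(nrow(scanGeneOverlaps(rec)), 0L)
})

test_that("the generator's configured overlaps are recovered exactly", {
  gm <- generateMitogenome(seed = 4)
  ov <- scanGeneOverlaps(gm$record)
  key <- paste(ov$gene_a, ov$gene_b)
  expect_setequal(key, c("ATP8 ATP6", "ATP6 COIII", "ND4L ND4", "ND5 ND6"))
  expect_equal(ov$overlap_length[key == "ATP8 ATP6"], 10L)
  expect_equal(ov$overlap_length[key == "ND4L ND4"], 7L)
  expect_equal(ov$overlap_length[key == "ND5 ND6"], 5L)
  expect_equal(ov$overlap_length[key == "ATP6 COIII"], 1L)
  expect_equal(ov$motif_class[key == "ATP8 ATP6"], "ATGGNNNTAA")
  # reported sequences agree with the generator's instantiated motifs
  tr <- gm$truth$overlaps
  expect_identical(
    ov$overlap_sequence[match(paste(tr$gene_a, tr$gene_b), key)],
    tr$overlap_sequence)
})

test_that("overlap scan agrees with a brute-force intersection oracle", {
  set.seed(42)
  for (iter in 1:6) {
    n <- sample(5:50, 1)
    starts <- sort(sample(0:900, n))
    ends <- starts + sample(5:80, n, replace = TRUE)
    ends <- pmin(ends, 1000L)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    nm <- paste0("g", seq_along(starts))
    ft <- data.frame(name = nm, strand = "H", start = starts, end = ends,
                     wraps_origin = FALSE)
    rec <- suppressWarnings(
      Mitogenome("RAND", randomDNAString(1000), ft))
    ov <- scanGeneOverlaps(rec)
    exp <- oracleIntersections(starts, ends)
    expect_equal(nrow(ov), nrow(exp))
    if (nrow(exp)) {
      got <- ov[order(ov$gene_a, ov$gene_b), ]
      expGenes <- data.frame(gene_a = nm[exp[, 1]], gene_b = nm[exp[, 2]],
                             len = exp[, 3])
      expGenes <- expGenes[order(expGenes$gene_a, expGenes$gene_b), ]
      expect_equal(got$overlap_length, expGenes$len)
    }
  }
})

test_that("an embedded O_L motif instance is found once, 26 nt pattern", {
  seq <- paste0(randomDNAString(150, seed = 9),
                "TTCCCCCGTTAGACTGAAAACGGGGG",
                randomDNAString(150, seed = 10))
  hits <- scanOLMotif(seq)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 150L)
  expect_equal(hits$pattern_length, 26L)
  expect_equal(hits$matched_motif, "ol26")
})

test_that("random sequence without the flanks has no O_L hits", {
  expect_equal(nrow(scanOLMotif(randomDNAString(2000, seed = 11))), 0L)
})

test_that("the two printed O_L patterns differ by a single edit", {
  expect_equal(unname(c(adist(olMotifs()[["ol26"]], olMotifs()[["ol25"]]))),
               1L)
})

test_that("an O_L motif crossing the origin of a circular genome is found", {
  motif <- "TTCCCCCGTTAGACTGAAAACGGGGG"
  body <- randomDNAString(300, seed = 12)
  # place the motif across the junction: last 10 nt + first 16 nt
  seq <- paste0(substr(motif, 11, 26), body, substr(motif, 1, 10))
  rec <- Mitogenome("CIRC", seq,
                    data.frame(name = "trnF", strand = "H", start = 0L,
                               end = 70L, wraps_origin = FALSE),
                    circular = TRUE)
  hits <- scanOLMotif(rec)
  expect_true(any(hits$start == nchar(seq) - 10L & hits$end == 16L))
})
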