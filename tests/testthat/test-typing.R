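# CR profiles and rule-table typing.

test_that("a full canonical layout with flanking repeats profiles as
           expected", {
  cr <- generateCR("eremias_typical", seed = 1)
  els <- annotateElements(cr$seq, restrictDownstream = FALSE)
  trs <- findTandemRepeats(cr$seq)
  prof <- buildProfile(els, trs, nchar(cr$seq), "eremias_cr")
  expect_true(all(unlist(prof[c("tas1", "tas2", "csb1", "csb2", "csb3")])))
  expect_true(prof$element_order_ok)
  expect_equal(prof$anormal, "-")
  expect_equal(prof$normal, "after_CSB3;before_TAS1")
  asg <- classifyCR(prof)
  expect_equal(asg$subtype, "I-4")
  expect_equal(asg$general_type, "I")
})

test_that("an empty annotation yields an all-absent, unclassified profile", {
  prof <- buildProfile(NULL, NULL, 150L, "empty")
  expect_false(any(unlist(prof[c("tas1", "tas2", "csb1", "csb2", "csb3")])))
  expect_equal(prof$anormal, "-")
  asg <- classifyCR(prof, defaultTypeRules()[0, ])
  expect_equal(asg$subtype, "unclassified")
})

test_that("duplicate element hits keep the best with a warning", {
  h1 <- fuzzyFind(paste0("CATACATTAA", randomDNAString(30, seed = 2),
                         "CATACATTAA"), "TAS2")
  expect_gte(nrow(h1), 2L)
  expect_warning(prof <- buildProfile(h1, NULL, 50L, "dup"), "duplicate")
  expect_true(prof$tas2)
})

test_that("the 21 layout profiles classify to 21 distinct subtypes in 5
           general types matching the published membership", {
  prof <- subtypeProfiles()
  asg <- classifyProfiles(prof)
  expect_equal(nrow(asg), 21L)
  expect_equal(length(unique(asg$subtype)), 21L)
  expect_setequal(unique(asg$general_type), c("I", "II", "III", "IV", "V"))
  expect_identical(asg$subtype, prof$subtype)
  expect_identical(asg$general_type, prof$general_type)
  # general-type group sizes from the published subtype lists
  bytype <- tapply(prof$n_species, prof$general_type, sum)
  expect_equal(as.vector(bytype[c("I", "II", "III", "IV", "V")]),
               c(17, 17, 6, 2, 11))
  expect_equal(sum(prof$n_species), 53L)
})

test_that("classification is deterministic and rules are pairwise
           distinguishable", {
  prof <- subtypeProfiles()
  a1 <- classifyProfiles(prof)
  a2 <- classifyProfiles(prof)
  expect_identical(a1, a2)
  # no two rules accept the same fixture profile
  rules <- defaultTypeRules()
  for (i in seq_len(nrow(prof))) {
    row <- prof[i, , drop = FALSE]
    p <- data.frame(record_id = row$taxon, tas1 = row$tas1, tas2 = row$tas2,
                    csb1 = row$csb1, csb2 = row$csb2, csb3 = row$csb3,
                    element_order_ok = row$order_ok, anormal = row$anormal,
                    normal = row$normal, cr_length = NA_integer_)
    matches <- vapply(seq_len(nrow(rules)), function(k)
      classifyCR(p, rules[k, , drop = FALSE])$subtype != "unclassified",
      logical(1))
    expect_equal(sum(matches), 1L, info = row$subtype)
  }
})

test_that("every shipped subtype rule is realisable by the generator", {
  rules <- defaultTypeRules()
  for (i in seq_len(nrow(rules))) {
    sp <- crSpecForRule(rules[i, ])
    cr <- generateCR(sp, seed = 100 + i)
    els <- annotateElements(cr$seq, restrictDownstream = FALSE)
    trs <- findTandemRepeats(cr$seq)
    prof <- buildProfile(els, trs, nchar(cr$seq), rules$subtype[i])
    asg <- classifyCR(prof)
    expect_equal(asg$subtype, rules$subtype[i])
  }
})

test_that("the type map flags incomplete control regions as N.A.", {
  asg <- rbind(
    cbind(classifyCR(data.frame(record_id = "complete", tas1 = TRUE,
                                tas2 = TRUE, csb1 = TRUE, csb2 = TRUE,
                                csb3 = TRUE, element_order_ok = TRUE,
                                anormal = "-", normal = "-",
                                cr_length = 600L)),
          complete = TRUE),
    cbind(data.frame(record_id = "partial", general_type = "V",
                     subtype = "V-1", matched_rule = "V-1"),
          complete = FALSE))
  tab <- typeMapTable(asg)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$subtype[tab$taxon == "complete"], "I-1")
  expect_equal(tab$subtype[tab$taxon == "partial"], "N.A.")
  expect_equal(nrow(typeMapTable(asg[0, ])), 0L)
})
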