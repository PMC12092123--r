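test_that("qualitative labels score to the standard proportions", {
  expect_equal(scoreLabel("major"), 0.60)
  expect_equal(scoreLabel("common"), 0.20)
  expect_equal(scoreLabel("uncommon"), 0.05)
  expect_equal(scoreLabel("rare"), 0.01)
  expect_true(all(diff(unname(dietLabelScores())) < 0))
  err <- tryCatch(scoreLabel("dominant"), psVocabularyError = identity)
  expect_s3_class(err, "psVocabularyError")
  expect_identical(err$label, "dominant")
})

test_that("the worked seven-group example combines and normalizes correctly", {
  rep <- workedDietReports()
  est <- combineReports(rep$qual, rep$quant)
  expect_equal(unname(est[c("Coleoptera", "Dermaptera", "Diptera",
                            "Hymenoptera", "Araneae", "Hemiptera", "Isopoda")]),
               c(0.21, 0.21, 0.75, 0.05, 0.01, 0.21, 0.01))
  expect_equal(sum(est), 1.45)

  prof <- normalizeProfile(est, speciesName(rep$qual))
  expect_equal(sum(dietWeights(prof)), 1, tolerance = 1e-12)
  dw <- displayedWeights(prof)
  expect_equal(unname(dw["Coleoptera"]), 0.144)
  expect_equal(unname(dw["Diptera"]), 0.517)
  expect_equal(unname(dw["Hymenoptera"]), 0.034)
  expect_equal(unname(dw["Araneae"]), 0.007)
  expect_equal(sum(dw), 0.997)
})

test_that("label calibration uses co-reported quantitative values and can be disabled", {
  rep <- workedDietReports()
  ## 'common' calibrated from Coleoptera's 0.21; disabling falls back to 0.20
  est <- combineReports(rep$qual, rep$quant, calibrate = FALSE)
  expect_equal(unname(est["Dermaptera"]), 0.20)
  expect_equal(unname(est["Coleoptera"]), 0.21)  # quantitative always wins

  ## two quantitative taxa sharing a label calibrate to their mean
  q <- qualitativeDietReport("sp", c(a = "common", b = "common", c = "common"))
  p <- quantitativeDietReport("sp", c(a = 0.1, b = 0.3))
  expect_equal(unname(combineReports(q, p)["c"]), 0.2)
})

test_that("qual-only and quant-only reports pass through as scored", {
  q <- qualitativeDietReport("sp", c(gA = "major", gB = "rare"))
  est <- combineReports(q, quantitativeDietReport("sp"))
  expect_equal(unname(est[c("gA", "gB")]), c(0.60, 0.01))

  est2 <- combineReports(qualitativeDietReport("sp"),
                         quantitativeDietReport("sp", c(gA = 0.97)))
  expect_equal(unname(est2), 0.97)

  expect_error(combineReports(qualitativeDietReport("sp"),
                              quantitativeDietReport("sp")),
               class = "psValidationError")
  expect_error(combineReports(qualitativeDietReport("x", c(g = "major")),
                              quantitativeDietReport("y", c(g = 0.5))),
               class = "psValidationError")
})

test_that("re-applying the combination to its own output changes nothing", {
  q <- qualitativeDietReport("sp", c(gA = "major", gB = "rare", gC = "uncommon"))
  est <- combineReports(q, quantitativeDietReport("sp"))
  again <- combineReports(qualitativeDietReport("sp"), est)
  expect_identical(again, est)
})

test_that("normalization is proportional and rejects empty input", {
  expect_equal(unname(dietWeights(normalizeProfile(c(a = 0.5, b = 0.5)))),
               c(0.5, 0.5))
  expect_equal(unname(dietWeights(normalizeProfile(c(a = 2, b = 2, c = 4)))),
               c(0.25, 0.25, 0.5))
  expect_error(normalizeProfile(c(a = 0, b = 0)), class = "psDomainError")
  ## full-precision weights always sum to 1 regardless of display rounding
  for (seed in 1:10) {
    set.seed(seed)
    est <- runif(sample(2:8, 1))
    names(est) <- paste0("t", seq_along(est))
    expect_equal(sum(dietWeights(normalizeProfile(est))), 1, tolerance = 1e-9)
  }
})

test_that("diet class richness counts distinct mapped classes within 1..12", {
  cmap <- c(Coleoptera = "Insecta", Diptera = "Insecta", Araneae = "Arachnida")
  prof <- normalizeProfile(c(Coleoptera = 0.5, Diptera = 0.3, Araneae = 0.2))
  expect_identical(dietClassRichness(prof, cmap), 2L)
  expect_identical(dietClassRichness(normalizeProfile(c(Coleoptera = 1)), cmap), 1L)

  err <- tryCatch(dietClassRichness(normalizeProfile(c(Chilopoda = 1)), cmap),
                  psMappingError = identity)
  expect_s3_class(err, "psMappingError")
  expect_identical(err$taxon, "Chilopoda")

  big <- paste0("c", 1:13)
  w <- rep(1 / 13, 13); names(w) <- big
  bigmap <- big; names(bigmap) <- big
  expect_error(dietClassRichness(normalizeProfile(w), bigmap),
               class = "psDomainError")
})

test_that("diet-report tables build calibrated profiles per species", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,prey_taxon,rank,qual_label,quant_proportion",
               "Amaurobius similis,Coleoptera,order,common,0.21",
               "Amaurobius similis,Dermaptera,order,common,",
               "Amaurobius similis,Diptera,order,major,0.75",
               "Steatoda grossa,Isopoda,order,major,",
               "Steatoda grossa,Coleoptera,order,rare,"), path)
  profs <- profilesFromReports(readTable(path, "diet_reports"))
  expect_setequal(names(profs), c("Amaurobius similis", "Steatoda grossa"))
  w <- dietWeights(profs[["Amaurobius similis"]])
  expect_equal(unname(w["Dermaptera"]), 0.21 / (0.21 + 0.21 + 0.75))
  expect_equal(sum(dietWeights(profs[["Steatoda grossa"]])), 1)

  donated <- inheritDiet(profs[["Steatoda grossa"]], "Steatoda nobilis")
  expect_identical(speciesName(donated), "Steatoda nobilis")
  expect_identical(dietWeights(donated), dietWeights(profs[["Steatoda grossa"]]))
})
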