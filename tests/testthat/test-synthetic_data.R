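test_that("Yule trees are ultrametric, rescaled, and seed-reproducible", {
  cherry <- simulateTree(2, seed = 1, rootDepth = 120)
  expect_equal(nTips(cherry), 2L)
  expect_equal(treeDepth(cherry), 120)

  phy <- simulateTree(75, seed = 5)
  expect_equal(nTips(phy), 75L)
  d <- ape::node.depth.edgelength(asPhylo(phy))[1:75]
  expect_lt(diff(range(d)), 1e-9)
  expect_equal(max(d), 300)

  expect_identical(writeNewick(simulateTree(20, seed = 8)),
                   writeNewick(simulateTree(20, seed = 8)))
  expect_false(identical(writeNewick(simulateTree(20, seed = 8)),
                         writeNewick(simulateTree(20, seed = 9))))
  expect_error(simulateTree(1, seed = 1), class = "psDomainError")
})

test_that("simulated diets are valid profiles with realistic richness", {
  one <- simulateDiets("sp", preyTaxa = "Insecta", seed = 1)
  expect_equal(unname(dietWeights(one$sp)), 1)

  flat <- simulateDiets("sp", concentration = 1e6, seed = 2)
  w <- dietWeights(flat$sp)
  expect_lt(diff(range(w)), 0.05)  # Dirichlet limit: near-uniform

  diets <- simulateDiets(sprintf("s%03d", 1:200), seed = 3)
  for (p in diets) expect_true(validObject(p, test = TRUE))
  rich <- vapply(diets, function(p)
    dietClassRichness(p, preyClassMap()), integer(1))
  expect_true(all(rich >= 1 & rich <= 12))
  expect_gte(stats::median(rich), 3)
  expect_lte(stats::median(rich), 5)
  ## spiders: insects always present in the simulated diets
  expect_true(all(vapply(diets, function(p)
    "Insecta" %in% names(dietWeights(p)), logical(1))))
})

test_that("noiseless LD50 generation is exactly linear in the statistic", {
  truth <- defaultGroundTruth()
  truth$sigma2Animal <- truth$sigma2Species <- truth$sigma2Resid <- 0
  truth$betaMass <- 0.3
  phy <- simulateTree(30, seed = 14)
  traits <- simulateTraits(phy, truth, seed = 15)
  diets <- simulateDiets(tipLabels(phy), seed = 16)
  assays <- simulateLD50(phy, diets, traits, truth, seed = 17)
  assays$log10_mass <- log10(traits$body_mass_g[match(assays$species,
                                                      traits$species)])
  assays$silk <- traits$silk_use[match(assays$species, traits$species)]
  fit <- lm(log10_ld50 ~ d_ld50_diet_hmya + log10_mass + silk + route,
            data = assays)
  expect_equal(unname(coef(fit)["d_ld50_diet_hmya"]), truth$betaD,
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)["log10_mass"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["routethorax_cephalothorax"]), 2.01,
               tolerance = 1e-6)
  ## determinism of the full record table
  again <- simulateLD50(phy, diets, traits, truth, seed = 17)
  expect_identical(assays[names(again)], again)
})

test_that("yield simulation reproduces its exponent and flags degenerate masses", {
  phy <- simulateTree(47, seed = 18)
  traits <- simulateTraits(phy, seed = 19)
  exact <- simulateYield(traits, noiseSd = 0, seed = 20, nMeasures = 60)
  fit <- fitLogLogSlope(exact$body_mass_g, exact$venom_yield_mg)
  expect_equal(fit@exponent, 0.75, tolerance = 1e-10)

  ## sampling distribution of the estimate stays in a sane band
  inBand <- 0
  for (r in 1:200) {
    y <- simulateYield(traits, seed = 500 + r, nMeasures = 60)
    s <- fitLogLogSlope(y$body_mass_g, y$venom_yield_mg)@exponent
    if (s > 0.5 && s < 1.0) inBand <- inBand + 1
  }
  expect_gte(inBand / 200, 0.95)

  flat <- traits
  flat$body_mass_g <- rep(2, nrow(flat))
  y <- simulateYield(flat, seed = 21)
  expect_error(fitLogLogSlope(y$body_mass_g, y$venom_yield_mg),
               class = "psDomainError")
})

test_that("binary trait simulation hits its rate-0 and fast-rate limits", {
  phy <- simulateTree(40, seed = 22)
  frozen <- simulateBinaryTrait(phy, 0, seed = 23)
  expect_equal(length(unique(frozen)), 1L)

  freqs <- vapply(1:50, function(s) {
    mean(simulateBinaryTrait(simulateTree(100, seed = 600 + s), 10,
                             seed = 700 + s))
  }, numeric(1))
  expect_gt(mean(freqs), 0.4)
  expect_lt(mean(freqs), 0.6)

  expect_identical(simulateBinaryTrait(phy, 0.01, seed = 24),
                   simulateBinaryTrait(phy, 0.01, seed = 24))
})

test_that("assembled datasets have the study shape and pass schema validation", {
  ds <- simulateVenomData(seed = 99)
  expect_equal(nTips(ds@phylogeny), 75L)
  expect_equal(length(ds@diets), 64L)
  expect_equal(nrow(ds@yields), 60L)
  expect_equal(length(unique(ds@yields$species)), 47L)
  nPer <- table(ds@assays$species)
  expect_true(all(nPer >= 1 & nPer <= 5))
  expect_true(all(ds@assays$species %in% tipLabels(ds@phylogeny)))

  dir <- withr::local_tempdir()
  writeVenomData(ds, dir)
  expect_silent(readTable(file.path(dir, "assays.csv"), "assays"))
  expect_silent(readTable(file.path(dir, "traits.csv"), "traits"))
  expect_s4_class(readNewick(file.path(dir, "tree.nwk")),
                  "CalibratedPhylogeny")
})

test_that("the pipeline recovers the generating signal end to end", {
  ds <- simulateVenomData(seed = 123)
  d <- ds@assays
  d$log10_mass <- log10(ds@traits$body_mass_g[match(d$species,
                                                    ds@traits$species)])
  d$silk_use <- ds@traits$silk_use[match(d$species, ds@traits$species)]
  spec <- modelSpec("log10_ld50",
                    fixed = c("d_ld50_diet_hmya", "log10_mass", "silk_use",
                              "route"),
                    iterations = 20000L, burnin = 4000L, thin = 10L,
                    nChains = 1L, seed = 17L)
  s <- summarizePMM(fitPMM(d, spec, ds@phylogeny))
  fx <- s@fixed
  ## the generating prey-specificity slope and route contrasts are positive
  ## and detected; null mass and silk effects are not called significant
  expect_gt(fx["d_ld50_diet_hmya", "mean"], 0)
  expect_true(fx["d_ld50_diet_hmya", "significant"])
  expect_true(fx["routethorax_cephalothorax", "significant"])
  expect_gt(fx["routethorax_cephalothorax", "mean"], 1)
  expect_false(fx["log10_mass", "significant"])
})
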