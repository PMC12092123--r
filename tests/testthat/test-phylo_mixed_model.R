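test_that("phylogenetic correlation matrix encodes shared history", {
  star <- readNewick("(A:100,B:100,C:100);")
  expect_equal(phyloCorrelationMatrix(star), diag(3),
               ignore_attr = TRUE)

  phy <- readNewick("((A:100,B:100):200,C:300);")
  A <- phyloCorrelationMatrix(phy)
  expect_equal(A["A", "B"], 200 / 300, tolerance = 1e-12)
  expect_equal(A["A", "C"], 0)
  expect_equal(diag(A), c(A = 1, B = 1, C = 1))

  err <- tryCatch(phyloCorrelationMatrix(phy, c("A", "Z")),
                  psLookupError = identity)
  expect_s3_class(err, "psLookupError")
  expect_identical(err$taxon, "Z")
})

test_that("correlation matrix matches per-pair brute-force MRCA depths", {
  for (seed in 1:5) {
    phy <- simulateTree(8, seed = seed)
    A <- phyloCorrelationMatrix(phy)
    tips <- tipLabels(phy)
    for (i in 1:7) for (j in (i + 1):8) {
      shared <- bruteSharedDepth(asPhylo(phy), tips[i], tips[j])
      expect_equal(A[tips[i], tips[j]], shared / treeDepth(phy),
                   tolerance = 1e-9)
    }
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))
  }
})

test_that("R-hat separates converged from divergent chains", {
  set.seed(1)
  base <- rnorm(200)
  expect_lte(gelmanRubin(list(base, base, base)), 1.01)
  expect_gt(gelmanRubin(list(rnorm(50, 0, 0.1), rnorm(50, 100, 0.1))), 1.1)
  expect_error(gelmanRubin(list(base)), class = "psDomainError")
  expect_error(gelmanRubin(list(1:5, 1:4)), class = "psDomainError")
})

test_that("R-hat matches the between/within formula on a constructed pair", {
  ## chains 1..10 and 3..12: W = 55/6, B = 20,
  ## pooled = 0.9*W + B/10, R-hat = sqrt(pooled/W) = 1.057441...
  r <- gelmanRubin(list(1:10, 3:12))
  W <- (var(1:10) + var(3:12)) / 2
  B <- 10 * var(c(mean(1:10), mean(3:12)))
  expect_equal(r, sqrt((0.9 * W + B / 10) / W), tolerance = 1e-12)
  expect_equal(r, 1.0574407, tolerance = 1e-6)
})

test_that("an intercept-only model without random terms recovers the sample mean", {
  set.seed(5)
  d <- data.frame(y = rnorm(40, 3, 1))
  spec <- modelSpec("y", random = character(0), iterations = 6000L,
                    burnin = 1000L, thin = 5L, nChains = 1L, seed = 2L)
  fit <- fitPMM(d, spec)
  draws <- posteriorDraws(fit)[, "(Intercept)"]
  expect_lt(abs(mean(draws) - mean(d$y)), 3 * mcse(draws))
})

test_that("with variances pinned by strong priors beta matches closed-form GLS", {
  dat <- glsTestData(nSpecies = 15, seed = 31)
  oracle <- glsOracleFit(dat)
  spec <- modelSpec("log10_ld50", fixed = c("d_ld50_diet_hmya", "log10_mass"),
                    priors = strongPriors(dat$truth),
                    iterations = 6000L, burnin = 1000L, thin = 2L,
                    nChains = 1L, seed = 4L)
  fit <- fitPMM(dat$data, spec, dat$phy)
  draws <- posteriorDraws(fit)
  expect_lt(abs(mean(draws[, "var_animal"]) - dat$truth$sigma2Animal), 0.01)
  for (j in 1:3) {
    d <- draws[, j]
    expect_lt(abs(mean(d) - oracle$beta[j]), 3 * mcse(d))
  }
})

test_that("posterior for beta approaches the GLS oracle as chains lengthen", {
  dat <- glsTestData(nSpecies = 12, seed = 77)
  oracle <- glsOracleFit(dat)
  errs <- vapply(c(400L, 4000L, 40000L), function(n) {
    spec <- modelSpec("log10_ld50", fixed = c("d_ld50_diet_hmya", "log10_mass"),
                      priors = strongPriors(dat$truth),
                      iterations = n, burnin = n %/% 4L, thin = 1L,
                      nChains = 1L, seed = 6L)
    fit <- fitPMM(dat$data, spec, dat$phy)
    max(abs(colMeans(posteriorDraws(fit))[1:3] - oracle$beta))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("a null phylogenetic variance is recovered as near-zero h2", {
  ## a clean phylogenetic null: no between-species variance of any kind,
  ## so any posterior mass on the animal term is pure leakage
  truth <- defaultGroundTruth()
  truth$sigma2Animal <- 0
  truth$sigma2Species <- 0
  phy <- simulateTree(60, seed = 41)
  traits <- simulateTraits(phy, truth, seed = 42)
  diets <- simulateDiets(tipLabels(phy), seed = 43)
  assays <- simulateLD50(phy, diets, traits, truth, seed = 44)
  spec <- modelSpec("log10_ld50", fixed = c("d_ld50_diet_hmya", "route"),
                    iterations = 10000L, burnin = 2000L, thin = 5L,
                    nChains = 1L, seed = 8L)
  fit <- fitPMM(assays, spec, phy)
  s <- summarizePMM(fit)
  expect_lt(s@h2[["mean"]], 0.1)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  set.seed(9)
  d <- data.frame(y = rnorm(20), a = rnorm(20))
  d$b <- 2 * d$a
  spec <- modelSpec("y", fixed = c("a", "b"), random = character(0),
                    iterations = 200L, burnin = 50L, thin = 1L,
                    nChains = 1L, seed = 1L)
  err <- tryCatch(fitPMM(d, spec), psDomainError = identity)
  expect_s3_class(err, "psDomainError")
  expect_true("b" %in% err$columns)
})

test_that("fixed seeds make the full draw stream bit-reproducible", {
  dat <- glsTestData(nSpecies = 10, seed = 55)
  spec <- modelSpec("log10_ld50", fixed = "d_ld50_diet_hmya",
                    iterations = 1200L, burnin = 200L, thin = 2L,
                    nChains = 2L, seed = 3L)
  f1 <- fitPMM(dat$data, spec, dat$phy)
  f2 <- fitPMM(dat$data, spec, dat$phy)
  expect_identical(f1@draws, f2@draws)
})

test_that("h2 is insensitive to rescaling the response", {
  dat <- glsTestData(nSpecies = 15, seed = 63)
  spec <- modelSpec("log10_ld50", fixed = "d_ld50_diet_hmya",
                    iterations = 8000L, burnin = 2000L, thin = 3L,
                    nChains = 1L, seed = 11L)
  h2a <- summarizePMM(fitPMM(dat$data, spec, dat$phy))@h2[["mean"]]
  d2 <- dat$data
  d2$log10_ld50 <- d2$log10_ld50 * 7
  h2b <- summarizePMM(fitPMM(d2, spec, dat$phy))@h2[["mean"]]
  expect_lt(abs(h2a - h2b), 0.05)
})

test_that("posterior summaries apply the interval-excludes-zero rule and h2 identity", {
  mk <- function(m) {
    colnames(m) <- c("(Intercept)", "beta", "var_animal", "var_species", "var_resid")
    m
  }
  pos <- mk(cbind(rnorm(100, 5), abs(rnorm(100)) + 0.1,
                  rep(1, 100), rep(1, 100), rep(1, 100)))
  sym <- mk(cbind(rnorm(100, 5), seq(-1, 1, length.out = 100),
                  rep(1, 100), rep(1, 100), rep(1, 100)))
  spec <- modelSpec("y", fixed = "beta", iterations = 100L, burnin = 10L,
                    thin = 1L, nChains = 1L, seed = 1L)
  sPos <- summarizePMM(new("PMMFit", draws = list(pos), spec = spec,
                           species = character(0), nObs = 100L))
  expect_true(sPos@fixed["beta", "significant"])
  expect_equal(sPos@h2[["mean"]], 1 / 3, tolerance = 1e-12)
  sSym <- summarizePMM(new("PMMFit", draws = list(sym), spec = spec,
                           species = character(0), nObs = 100L))
  expect_false(sSym@fixed["beta", "significant"])
  sRes <- summarizePMM(new("PMMFit", draws = list(pos), spec = spec,
                           species = character(0), nObs = 100L),
                       h2Denominator = "animal_resid")
  expect_equal(sRes@h2[["mean"]], 1 / 2, tolerance = 1e-12)
  expect_error(summarizePMM(new("PMMFit", draws = list(pos[0, , drop = FALSE]),
                                spec = spec, species = character(0),
                                nObs = 0L)),
               class = "psDomainError")
})

test_that("R-hat agrees with the reference implementation on real chains", {
  dat <- glsTestData(nSpecies = 10, seed = 21)
  spec <- modelSpec("log10_ld50", fixed = "d_ld50_diet_hmya",
                    iterations = 3000L, burnin = 500L, thin = 2L,
                    nChains = 3L, seed = 13L)
  fit <- fitPMM(dat$data, spec, dat$phy)
  ch <- lapply(fit@draws, function(m) m[, "d_ld50_diet_hmya"])
  ml <- coda::mcmc.list(lapply(ch, coda::mcmc))
  ref <- as.numeric(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
  ## coda adds a sampling-variability correction term; agreement is close
  ## but not exact for finite chains
  expect_equal(gelmanRubin(ch), ref, tolerance = 0.02)
})
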