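test_that("library entries are deterministic, ordered by mobility, and Rayleigh for pure noise", {
  cfgFree <- freeConfig()
  lib <- buildModelLibrary(c(1e-6, 4.3), c(50, 75), cfgFree,
                           nTraj = 2000, seed = 1, binEdges = prEdges())
  lib2 <- buildModelLibrary(c(1e-6, 4.3), c(50, 75), cfgFree,
                            nTraj = 2000, seed = 1, binEdges = prEdges())
  expect_identical(lib@entries, lib2@entries)  # bit-for-bit given seed

  # D ~ 0: displacement is the difference of two noise draws,
  # Rayleigh with scale sqrt(2) sigma; mean = scale sqrt(pi/2)
  e0 <- libraryEntry(lib, 1e-6, 50)
  meanR <- sum(binCenters(e0) * probability(e0))
  expect_equal(meanR, sqrt(2) * 0.05 * sqrt(pi / 2), tolerance = 0.03)

  # monotonicity: slow/low-noise entry has smaller mean displacement
  eS <- libraryEntry(lib, 1e-6, 50)
  eF <- libraryEntry(lib, 4.3, 75)
  expect_lt(sum(binCenters(eS) * probability(eS)),
            sum(binCenters(eF) * probability(eF)))
  expect_error(libraryEntry(lib, 2.2, 50), "no library entry")
  expect_error(buildModelLibrary(1, 50, stdConfig(), nTraj = 100,
                                 seed = 1, binEdges = prEdges()),
               "10,000 steps")
})

test_that("reducedChiSquare is zero on identity and ~1 under the null", {
  d <- displacementPdf(stats::rweibull(2000, 2, 0.2), 0.025, 1.2)
  expect_equal(reducedChiSquare(d, d, 1), 0)
  dd <- displacementPdf(stats::rweibull(2000, 2, 0.2), 0.025, 0.8)
  expect_error(reducedChiSquare(d, dd, 1), "mismatched binning")

  # two independent simulations of the same model: chi2nu in [0.5, 1.5]
  m <- efpStaticModel()
  chis <- vapply(1:4, function(s) {
    a <- simulateEnsemble(m, stdConfig(), 8400, seed = s, static = TRUE)
    b <- simulateEnsemble(m, stdConfig(), 8400, seed = 100 + s,
                          static = TRUE)
    da <- displacementPdf(singleStepDisplacements(a), 0.025, 1.2)
    db <- displacementPdf(singleStepDisplacements(b), 0.025, 1.2)
    reducedChiSquare(da, db, 0)
  }, numeric(1))
  expect_true(all(chis > 0.4 & chis < 1.6))
  expect_gt(mean(chis), 0.5)
  expect_lt(mean(chis), 1.5)

  # nu <= 0 error
  tiny <- displacementPdf(c(0.1, 0.11), 0.2, 0.4)
  expect_error(reducedChiSquare(tiny, tiny, 5), "nu <= 0")
})

test_that("one-state self-fit recovers the generating D", {
  lib <- efpLibrary()
  Dtrue <- lib@Dgrid[which.min(abs(lib@Dgrid - 0.8))]
  m <- TwoStateModel(Dtrue, Dtrue, fSlow = 1, sigmaSlow = 75,
                     sigmaFast = 75)
  ts <- simulateEnsemble(m, stdConfig(), 2000, seed = 21, static = TRUE)
  pr <- displacementPdf(singleStepDisplacements(ts), 0.025, 1.2)
  fit <- fitStatic(pr, lib, nStates = 1, sigmaFast = 75)$fit
  expect_equal(fit@Dfast, Dtrue, tolerance = 0.10)
  expect_identical(fit@nStates, 1L)
})

test_that("a wrong single-state model is rejected with a large chi2nu", {
  lib <- efpLibrary()
  ts <- simulateEnsemble(efpStaticModel(), stdConfig(), 867, seed = 22,
                         static = TRUE)
  pr <- displacementPdf(singleStepDisplacements(ts), 0.025, 1.2)
  one <- fitStatic(pr, lib, nStates = 1, sigmaFast = 75)$fit
  two <- fitStatic(pr, lib, nStates = 2, sigmaSlow = 50, sigmaFast = 75,
                   DslowFixed = 0.2)$fit
  expect_gt(one@chi2nu, 5)          # all single-population fits are poor
  expect_lt(two@chi2nu, 2.5)
  expect_gt(one@chi2nu, 3 * two@chi2nu)
})

test_that("the mixture with fSlow = 0 equals the pure fast entry", {
  lib <- efpLibrary()
  eF <- libraryEntry(lib, lib@Dgrid[30], 75)
  target <- new("DisplacementDistribution", binEdges = lib@binEdges,
                counts = binCounts(eF), nTotal = eF@nTotal,
                kind = "single_step")
  fit <- fitStatic(target, lib, nStates = 2, sigmaSlow = 50,
                   sigmaFast = 75, DslowFixed = 0.2, fSlowFixed = 0,
                   DfastFixed = lib@Dgrid[30])$fit
  expect_equal(fit@chi2nu, 0)
})

test_that("unconstrained two-state fit recovers a ribosome-like mixture", {
  # slow 70S polysomes (0.2) + free subunits (0.8), f_slow = 0.65,
  # at the sample size of a 15,800-trajectory study
  cfg <- stdConfig()
  rib <- TwoStateModel(0.2, 0.8, fSlow = 0.65, sigmaSlow = 40,
                       sigmaFast = 75)
  lib <- buildModelLibrary(defaultDGrid(0.05, 3), c(40, 75), cfg,
                           nTraj = 8000, seed = 42, binEdges = prEdges())
  step <- lib@Dgrid[2] / lib@Dgrid[1]
  hits <- vapply(1:3, function(s) {
    ts <- simulateEnsemble(rib, cfg, 15800, seed = s, static = TRUE)
    pr <- displacementPdf(singleStepDisplacements(ts), 0.025, 1.2)
    f <- fitStatic(pr, lib, nStates = 2, sigmaSlow = 40,
                   sigmaFast = 75)$fit
    ok <- abs(log(f@Dslow / 0.2)) <= 2.05 * log(step) &&
      abs(log(f@Dfast / 0.8)) <= 2.05 * log(step) &&
      abs(f@fSlow - 0.65) <= 0.05
    expect_lt(f@chi2nu, 1.5)
    ok
  }, logical(1))
  # the slow component is noise-dominated (rms step 40 nm under a 40 nm
  # sigma), so occasional excursions are expected; majority must recover
  expect_gte(sum(hits), 2)
})

test_that("confidenceRegion extracts chi2nu <= 1.5 parameter ranges", {
  g <- new("ChiSqGrid", axes = list(D = c(1, 2, 3)),
           values = array(c(3, 1.2, 4), dim = 3))
  cr <- confidenceRegion(g)
  expect_equal(unname(cr$D), c(2, 2))  # single sub-threshold point
  expect_error(confidenceRegion(g, threshold = 1), "no grid points")

  # EF-P-like grid: f_slow range spans roughly 0.2-0.4 around the fit
  lib <- efpLibrary()
  ts <- simulateEnsemble(efpStaticModel(), stdConfig(), 867, seed = 1,
                         static = TRUE)
  pr <- displacementPdf(singleStepDisplacements(ts), 0.025, 1.2)
  res <- fitStatic(pr, lib, nStates = 2, sigmaSlow = 50, sigmaFast = 75,
                   DslowFixed = 0.2)
  cr2 <- confidenceRegion(res$grid, 1.5)
  expect_lte(cr2$fSlow["min"], 0.30)
  expect_gte(cr2$fSlow["max"], 0.30)
  expect_gte(cr2$fSlow["min"], 0.10)
  expect_lte(cr2$fSlow["max"], 0.50)
})

test_that("predictSixStepStatic delegates to the ensemble simulator", {
  fit <- new("StaticFit", nStates = 2L, Dslow = 0.2, Dfast = 4.3,
             fSlow = 0.3, fFast = 0.7, sigmaSlow = 50, sigmaFast = 75,
             chi2nu = 1, constrained = c(Dslow = TRUE, Dfast = FALSE,
                                         fSlow = FALSE),
             onBoundary = FALSE)
  pred <- predictSixStepStatic(fit, stdConfig(), 2000, seed = 31)
  states <- rep(c(1L, 0L), c(600, 1400))
  ref <- simulateEnsemble(efpStaticModel(), stdConfig(), 2000, seed = 31,
                          static = TRUE, fixedState = states)
  refPdf <- displacementPdf(meanSixStep(ref), 0.025, 0.8,
                            kind = "six_step_mean")
  expect_identical(binCounts(pred), binCounts(refPdf))

  # f_slow = 1: unimodal slow distribution
  fit1 <- new("StaticFit", nStates = 2L, Dslow = 0.2, Dfast = 4.3,
              fSlow = 1, fFast = 0, sigmaSlow = 50, sigmaFast = 75,
              chi2nu = 1, constrained = c(Dslow = TRUE, Dfast = FALSE,
                                          fSlow = TRUE),
              onBoundary = FALSE)
  p1 <- predictSixStepStatic(fit1, stdConfig(), 4000, seed = 32)
  ts1 <- simulateEnsemble(TwoStateModel(0.2, 4.3, fSlow = 1,
                                        sigmaSlow = 50, sigmaFast = 75),
                          stdConfig(), 4000, seed = 32, static = TRUE)
  expect_identical(densityModes(meanSixStep(ts1))$nModes, 1L)
  expect_equal(sum(probability(p1)), 1)
})

test_that("fitLifetimes pushes a static target to the slow-exchange limit", {
  base <- new("StaticFit", nStates = 2L, Dslow = 0.2, Dfast = 4.3,
              fSlow = 0.3, fFast = 0.7, sigmaSlow = 50, sigmaFast = 75,
              chi2nu = 1, constrained = c(Dslow = TRUE, Dfast = FALSE,
                                          fSlow = FALSE),
              onBoundary = FALSE)
  ts <- simulateEnsemble(efpStaticModel(), stdConfig(), 2000, seed = 41,
                         static = TRUE)
  r6 <- displacementPdf(meanSixStep(ts), 0.025, 0.8,
                        kind = "six_step_mean")
  res <- fitLifetimes(r6, base, tauGrid = c(0.1, 1, 10, 100),
                      config = stdConfig(), nTraj = 6000, seed = 42,
                      refine = FALSE)
  chi <- as.numeric(res$grid@values)
  expect_identical(res$fit@tauFree, 100)     # slow-exchange end wins
  expect_gt(chi[1], chi[4])                  # fast exchange fits worse
  expect_equal(res$fit@tauFree / res$fit@tauBound, 0.7 / 0.3)
})
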