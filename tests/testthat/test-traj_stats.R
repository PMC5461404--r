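mkTraj <- function(xy, trajId = 1L, cellId = "c1") {
  data.frame(cell_id = cellId, traj_id = trajId,
             frame = seq_len(nrow(xy)) - 1L, x = xy[, 1], y = xy[, 2])
}

test_that("filterByLength keeps >= minFrames trajectories exactly", {
  lens <- 3:12
  rec <- do.call(rbind, lapply(seq_along(lens), function(i)
    mkTraj(matrix(0, lens[i], 2), trajId = i)))
  ts <- TrajectorySet(rec)
  kept <- filterByLength(ts, 7)
  expect_setequal(unique(records(kept)$traj_id), which(lens >= 7))
  expect_identical(nTrajectories(filterByLength(ts, 7)), 6L)
  # boundary: the 6-frame trajectory is dropped, the 7-frame one kept
  expect_false(4L %in% records(kept)$traj_id)
  expect_true(5L %in% records(kept)$traj_id)
  expect_true(all(table(records(kept)$traj_id) >= 7))
})

test_that("singleStepDisplacements computes per-pair 2D magnitudes", {
  still <- TrajectorySet(mkTraj(matrix(0, 8, 2)))
  expect_true(all(singleStepDisplacements(still) == 0))
  tri <- TrajectorySet(mkTraj(rbind(c(0, 0), c(0.3, 0.4))))
  expect_equal(singleStepDisplacements(tri), 0.5)
  # count = sum(len_i - 1); 859 seven-frame trajectories -> 5154 steps
  rec <- do.call(rbind, lapply(1:859, function(i)
    mkTraj(matrix(rnorm(14), 7, 2), trajId = i)))
  expect_identical(length(singleStepDisplacements(TrajectorySet(rec))),
                   859L * 6L)
})

test_that("meanSixStep averages the first six steps only", {
  # steps 0.1..0.6 along x
  xs <- cumsum(c(0, (1:6) / 10))
  ts <- TrajectorySet(mkTraj(cbind(xs, 0)))
  expect_equal(meanSixStep(ts), 0.35)
  # constant-step trajectory
  ts2 <- TrajectorySet(mkTraj(cbind(seq(0, by = 0.2, length.out = 9), 0)))
  expect_equal(meanSixStep(ts2), 0.2)
  # truncation contract: steps 7+ are ignored
  xs12 <- c(xs, xs[7] + cumsum(rep(5, 6)))
  ts3 <- TrajectorySet(mkTraj(cbind(xs12, 0)))
  expect_equal(meanSixStep(ts3), 0.35)
  # short trajectories skipped with a warning
  recs <- rbind(mkTraj(cbind(xs, 0), 1L), mkTraj(matrix(0, 4, 2), 2L))
  expect_warning(v <- meanSixStep(TrajectorySet(recs)), "skipped")
  expect_equal(v, 0.35)
})

test_that("displacementPdf bins, normalizes and conserves counts", {
  d <- displacementPdf(0.05, binWidth = 0.025, rMax = 0.2)
  expect_equal(sum(binCounts(d)), 1)
  expect_equal(binCounts(d)[3], 1)  # [0.05, 0.075)
  expect_error(displacementPdf(numeric(0)), "empty")
  set.seed(1)
  v <- runif(5000, 0, 2)  # beyond rMax -> last bin
  d2 <- displacementPdf(v, 0.025, 1.2)
  expect_equal(sum(binCounts(d2)), 5000)
  expect_equal(sum(probability(d2)), 1)
})

test_that("displacementPdf of a Rayleigh sample matches the analytic integral", {
  s <- 0.1687
  set.seed(2)
  v <- s * sqrt(-2 * log(runif(100000)))
  d <- displacementPdf(v, 0.025, 1.2)
  e <- binEdges(d)
  cdf <- function(q) 1 - exp(-q^2 / (2 * s^2))
  p <- diff(cdf(e)); p[length(p)] <- p[length(p)] + 1 - cdf(e[length(e)])
  keep <- 100000 * p >= 5
  chi <- sum((binCounts(d)[keep] - 100000 * p[keep])^2 /
               (100000 * p[keep])) / (sum(keep) - 1)
  expect_gt(chi, 0.4)
  expect_lt(chi, 1.8)
})

test_that("msdCurve follows the free-diffusion law with noise offset", {
  frozen <- TrajectorySet(mkTraj(matrix(0, 7, 2)))
  expect_true(all(msdCurve(frozen)@msd == 0))

  m0 <- TwoStateModel(1, 1, fSlow = 1, sigmaSlow = 0, sigmaFast = 0)
  ts0 <- simulateEnsemble(m0, freeConfig(), 8000, seed = 3, static = TRUE)
  c0 <- msdCurve(ts0)
  expect_equal(c0@msd, 4 * 1 * c0@lag * 1e-3, tolerance = 0.03)

  m1 <- TwoStateModel(1, 1, fSlow = 1, sigmaSlow = 50, sigmaFast = 50)
  ts1 <- simulateEnsemble(m1, freeConfig(), 8000, seed = 3, static = TRUE)
  c1 <- msdCurve(ts1)
  expect_equal(c1@msd - c0@msd, rep(4 * 0.05^2, 6), tolerance = 0.12)
})

test_that("dSigmaFromMsd inverts the two-point line", {
  cv <- new("MSDCurve", lag = c(2, 4), msd = c(0.018, 0.034),
            sem = c(0, 0), nPairs = c(10L, 10L))
  est <- dSigmaFromMsd(cv)
  expect_equal(est$D, 2.0)
  expect_equal(est$sigma, sqrt(0.002 / 4) * 1000, tolerance = 1e-9)
  # pure noise: flat MSD = 4 sigma^2
  cvn <- new("MSDCurve", lag = c(2, 4), msd = rep(4 * 0.05^2, 2),
             sem = c(0, 0), nPairs = c(10L, 10L))
  estn <- dSigmaFromMsd(cvn)
  expect_equal(estn$D, 0)
  expect_equal(estn$sigma, 50)
  # negative intercept clamps sigma with a flag
  cvneg <- new("MSDCurve", lag = c(2, 4), msd = c(0.01, 0.03),
               sem = c(0, 0), nPairs = c(10L, 10L))
  expect_true(dSigmaFromMsd(cvneg)$sigmaClamped)
})

test_that("an exchange ensemble reproduces the occupancy-weighted mean D", {
  # kinetic averaging: MSD slope of the unconfined two-state ensemble
  ts <- simulateEnsemble(efpModel(), freeConfig(), 10000, seed = 4)
  est <- dSigmaFromMsd(msdCurve(ts))
  expect_equal(est$D, 3.4, tolerance = 0.15)
})

test_that("stepwiseDSelection separates slow and fast subpopulations", {
  # 10 distinct trajectories, quantile 0.1 -> one at each extreme
  rec <- do.call(rbind, lapply(1:10, function(i)
    mkTraj(cbind(seq(0, by = 0.01 * i, length.out = 7), 0), trajId = i)))
  sel <- stepwiseDSelection(TrajectorySet(rec), 0.10)
  expect_identical(nTrajectories(sel$slow), 1L)
  expect_identical(unique(records(sel$slow)$traj_id), 1L)
  expect_identical(unique(records(sel$fast)$traj_id), 10L)
  expect_lt(sel$cutoffs["slow"], sel$cutoffs["fast"])

  # degenerate ties: stable selection by trajectory order
  recT <- do.call(rbind, lapply(1:5, function(i)
    mkTraj(cbind(seq(0, by = 0.1, length.out = 7), 0), trajId = i)))
  selT <- stepwiseDSelection(TrajectorySet(recT), 0.2)
  expect_identical(unique(records(selT$slow)$traj_id), 1L)
  expect_equal(unname(selT$cutoffs["slow"]), unname(selT$cutoffs["fast"]))

  # two-state static ensemble: slow subset MSD-D well below fast subset
  ts <- simulateEnsemble(efpStaticModel(), stdConfig(), 3000, seed = 5,
                         static = TRUE)
  sel2 <- stepwiseDSelection(ts, 0.10)
  dSlow <- dSigmaFromMsd(msdCurve(sel2$slow))$D
  dFast <- dSigmaFromMsd(msdCurve(sel2$fast))$D
  expect_lt(dSlow, dFast / 4)
})

test_that("P(<r>6) is narrower than P(r) for the same population", {
  ts <- simulateEnsemble(efpStaticModel(), stdConfig(), 4000, seed = 6,
                         static = TRUE)
  expect_lt(var(meanSixStep(ts)), var(singleStepDisplacements(ts)))
})

test_that("msdCurve of a concatenation is the pair-weighted mean of parts", {
  m <- TwoStateModel(1, 1, fSlow = 1, sigmaSlow = 30, sigmaFast = 30)
  a <- simulateEnsemble(m, stdConfig(), 300, seed = 7, static = TRUE)
  b <- simulateEnsemble(m, stdConfig(), 500, seed = 8, static = TRUE)
  rb <- records(b); rb$traj_id <- rb$traj_id + 1000L
  both <- TrajectorySet(rbind(records(a), rb))
  ca <- msdCurve(a); cb <- msdCurve(b); cc <- msdCurve(both)
  wmean <- (ca@msd * ca@nPairs + cb@msd * cb@nPairs) /
    (ca@nPairs + cb@nPairs)
  expect_equal(cc@msd, wmean, tolerance = 1e-12)
})

test_that("axialDistribution pools scaled positions and rejects outliers", {
  cells <- data.frame(cell_id = c("a", "b"), length_um = c(4, 6),
                      diameter_um = 0.9)
  rec <- rbind(mkTraj(cbind(c(0, 0.5, 1, 1.5, 1.9, 1.0, 0), rep(0, 7)),
                      1L, "a"),
               mkTraj(cbind(rep(2.9, 7), rep(0, 7)), 2L, "b"))
  ts <- TrajectorySet(rec)
  ax <- axialDistribution(ts, cells, nBins = 10)
  expect_equal(sum(probability(ax)), 1)
  # cell b positions 2.9/6 ~ 0.483 and cell a's 1.9/4 = 0.475 -> last bin
  expect_equal(probability(ax)[10], 8 / 14)
  # restrict to the 3.5-4.5 um window: only cell a remains
  ax2 <- axialDistribution(ts, cells, nBins = 10, lengthRange = c(3.5, 4.5))
  expect_equal(sum(probability(ax2)), 1)
  # outside-cell localization rejected with warning
  rec2 <- rec; rec2$x[1] <- 2.2
  expect_warning(axialDistribution(TrajectorySet(rec2), cells, nBins = 10),
                 "rejected 1")
})
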