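# render a single integrated-Gaussian spot on a blank frame
renderSpot <- function(n, cx, cy, sigmaPx, photons) {
  edges <- (0:n) - 0.5
  fx <- diff(stats::pnorm(edges, cx, sigmaPx))
  fy <- diff(stats::pnorm(edges, cy, sigmaPx))
  photons * outer(fy, fx)
}

test_that("preprocessFrame smooths, zero-bases and clamps", {
  expect_true(all(preprocessFrame(matrix(7, 16, 16)) == 0))
  img <- matrix(0, 21, 21); img[11, 11] <- 90
  z <- preprocessFrame(img)
  expect_equal(z[11, 11], 10)   # 3x3 boxcar: A/9, median background 0
  expect_equal(z[11, 12], 10)
  expect_equal(z[9, 9], 0)
  expect_true(all(preprocessFrame(matrix(rnorm(400), 20, 20)) >= 0))
})

test_that("detectPeaks finds distinct maxima and honors the threshold", {
  expect_identical(nrow(detectPeaks(matrix(1, 16, 16), 0.5)), 0L)
  img <- renderSpot(64, 20, 30, 1.2, 3000) + renderSpot(64, 40, 30, 1.2, 2500)
  pk <- detectPeaks(img, threshold = 10)
  expect_identical(nrow(pk), 2L)
  expect_setequal(pk$col + 0L, c(21L, 41L))  # 1-based indices
  expect_setequal(pk$row + 0L, c(31L, 31L))
  expect_identical(nrow(detectPeaks(img, threshold = 2 * max(img))), 0L)
  # peaks closer than 4 px merge, keeping the brighter
  img2 <- renderSpot(64, 20, 30, 1.0, 3000) + renderSpot(64, 22, 30, 1.0, 1000)
  pk2 <- detectPeaks(img2, threshold = 5)
  expect_identical(nrow(pk2), 1L)
  expect_identical(pk2$col, 21L)
})

test_that("centroidLocalize recovers pixel-centred and subpixel positions", {
  img <- renderSpot(64, 30, 40, 1.2, 5000)
  loc <- centroidLocalize(img, list(row = 41L, col = 31L), pixelSize = 160)
  expect_equal(loc$x_um, 30 * 0.16, tolerance = 1e-6)
  expect_equal(loc$y_um, 40 * 0.16, tolerance = 1e-6)
  # known +0.3 px x-offset recovered within 0.1 px
  img2 <- renderSpot(64, 30.3, 40, 1.2, 50000)
  loc2 <- centroidLocalize(img2, list(row = 41L, col = 31L), pixelSize = 160)
  expect_equal(loc2$x_um / 0.16, 30.3, tolerance = 0.1 / 30.3)
  expect_error(centroidLocalize(img * 0, list(row = 41L, col = 31L)),
               "zero total intensity")
  expect_error(centroidLocalize(img, list(row = 2L, col = 31L)),
               "window outside")
})

test_that("a motion-blurred spot localizes at the time-averaged position", {
  # emitter sliding from x = 28 to 32 px during the exposure
  xs <- seq(28, 32, length.out = 20)
  img <- Reduce(`+`, lapply(xs, function(x) renderSpot(64, x, 40, 1.2, 500)))
  pk <- detectPeaks(img, threshold = 1)
  loc <- centroidLocalize(img, list(row = pk$row[1], col = pk$col[1]),
                          pixelSize = 160)
  expect_equal(loc$x_um / 0.16, mean(xs), tolerance = 0.02)
})

# exhaustive maximal matching oracle, written independently of the
# implementation: enumerate all injective candidate->previous maps
bruteMatch <- function(px, py, cx, cy, maxDisp) {
  nP <- length(px); nC <- length(cx)
  cost <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
  opts <- lapply(seq_len(nC), function(ci)
    c(0L, which(cost[, ci] <= maxDisp^2)))
  best <- NULL
  grids <- expand.grid(opts)
  for (i in seq_len(nrow(grids))) {
    asg <- as.integer(grids[i, ])
    used <- asg[asg > 0]
    if (anyDuplicated(used)) next
    nM <- length(used)
    tc <- sum(vapply(seq_len(nC), function(ci)
      if (asg[ci] > 0) cost[asg[ci], ci] else 0, numeric(1)))
    if (is.null(best) || nM > best$n ||
        (nM == best$n && tc < best$cost - 1e-12)) {
      best <- list(n = nM, cost = tc, assign = asg)
    }
  }
  best
}

test_that("linking matches the brute-force minimum-cost assignment", {
  set.seed(9)
  for (rep in 1:20) {
    nP <- sample(1:4, 1); nC <- sample(1:4, 1)
    px <- runif(nP, 0, 3); py <- runif(nP, 0, 3)
    cx <- runif(nC, 0, 3); cy <- runif(nC, 0, 3)
    got <- sptKinetics:::.matchFrames(px, py, cx, cy, maxDisp = 1.2)
    want <- bruteMatch(px, py, cx, cy, maxDisp = 1.2)
    nGot <- sum(got > 0)
    cGot <- sum(vapply(seq_len(nC), function(ci)
      if (got[ci] > 0) (px[got[ci]] - cx[ci])^2 + (py[got[ci]] - cy[ci])^2
      else 0, numeric(1)))
    expect_identical(nGot, want$n)
    expect_equal(cGot, want$cost, tolerance = 1e-9)
  }
})

test_that("linkLocalizations builds trajectories with the expected topology", {
  # two spots far apart: two parallel trajectories, never merged
  locs <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, x_um = c(1, 10) + 0.01 * f, y_um = c(1, 10))))
  ts <- linkLocalizations(locs, maxDisp = 0.5)
  expect_identical(nTrajectories(ts), 2L)
  expect_true(all(table(records(ts)$traj_id) == 10))

  # single drifting spot (1 px/frame << maxDisp): one full trajectory
  drift <- data.frame(frame = 0:19, x_um = 0.16 * (0:19), y_um = 2)
  ts2 <- linkLocalizations(drift, maxDisp = 0.8)
  expect_identical(nTrajectories(ts2), 1L)
  expect_identical(nrow(records(ts2)), 20L)

  # a missed frame ends the trajectory (memory = 0)
  gap <- drift[-10, ]
  ts3 <- linkLocalizations(gap, maxDisp = 0.8)
  expect_identical(nTrajectories(ts3), 2L)

  # permutation invariance of the input order
  shuf <- locs[sample(nrow(locs)), ]
  tsS <- linkLocalizations(shuf, maxDisp = 0.5)
  a <- records(ts); b <- records(tsS)
  key <- function(r) paste(r$frame, round(r$x, 9), round(r$y, 9))
  grp <- function(r) split(key(r), r$traj_id)
  expect_setequal(unname(vapply(grp(a), paste, "", collapse = ";")),
                  unname(vapply(grp(b), paste, "", collapse = ";")))
})

test_that("renderMovie conserves photons and supports noise models", {
  cfg <- SimConfig(nFrames = 3, cell = Spherocylinder(4, 0.9))
  frozen <- TwoStateModel(0, 0, fSlow = 1)
  r0 <- renderMovie(frozen, cfg, nEmitters = 1, photonsPerFrame = 4000,
                    background = 0, seed = 2, noise = FALSE)
  sums <- vapply(r0$movie@frames, sum, numeric(1))
  expect_equal(sums, rep(4000, 3), tolerance = 1e-3)  # +-4 sigma PSF window

  # zero photons: pure background noise at the Poisson mean
  rb <- renderMovie(frozen, cfg, nEmitters = 1, photonsPerFrame = 0,
                    background = 3, seed = 2, noise = TRUE)
  expect_equal(mean(rb$movie@frames[[1]]), 3, tolerance = 0.05)
  expect_identical(renderMovie(frozen, cfg, 1, photonsPerFrame = 0,
                               background = 3, seed = 2)$movie@frames,
                   rb$movie@frames)

  # localization count per frame bounded by emitter count when the
  # threshold clears the background
  m <- TwoStateModel(1, 1, fSlow = 1)
  cfg2 <- SimConfig(nFrames = 10, cell = Spherocylinder(6, 0.9))
  rm2 <- renderMovie(m, cfg2, nEmitters = 2, photonsPerFrame = 8000,
                     background = 4, seed = 3)
  locs <- localizeMovie(rm2$movie, threshold = 40)
  expect_true(all(table(locs$frame) <= 2))
})

test_that("movies survive a TIFF round trip", {
  cfg <- SimConfig(nFrames = 2, cell = Spherocylinder(4, 0.9))
  r0 <- renderMovie(TwoStateModel(0.5, 0.5, fSlow = 1), cfg, 1,
                    photonsPerFrame = 1000, background = 2, seed = 4)
  path <- tempfile(fileext = ".tif")
  writeMovieTiff(r0$movie, path)
  back <- readMovieTiff(path)
  expect_equal(back@frames, r0$movie@frames, tolerance = 1e-6)
  unlink(c(path, paste0(path, ".scale")))
})
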