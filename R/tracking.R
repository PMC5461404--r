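#' Construct a movie
#'
#' @param frames list of non-negative intensity matrices (constant shape).
#' @param pixelSize nm per pixel (default 160).
#' @param frameInterval ms (default 2).
#' @return a [Movie-class].
#' @export
Movie <- function(frames, pixelSize = 160, frameInterval = 2) {
  new("Movie", frames = frames, pixelSize = pixelSize,
      frameInterval = frameInterval)
}

setMethod("show", "Movie", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("Movie: %d frames of %dx%d px (%g nm/px, %g ms/frame)\n",
              length(object@frames), d[1], d[2], object@pixelSize,
              object@frameInterval))
})

#' Write / read a movie as multi-page TIFF
#'
#' Intensities are stored as 32-bit floats.
#' @param movie a [Movie-class].
#' @param path file path.
#' @param pixelSize,frameInterval metadata for [readMovieTiff()] (TIFF
#'   stores none).
#' @return `readMovieTiff` returns a [Movie-class].
#' @export
writeMovieTiff <- function(movie, path) {
  tiff::writeTIFF(lapply(movie@frames, function(f) f / max(1, max(f))),
                  path, bits.per.sample = 32L, reduce = FALSE)
  # scale factors stored alongside to keep absolute counts
  scl <- vapply(movie@frames, function(f) max(1, max(f)), numeric(1))
  writeLines(format(scl, digits = 17), paste0(path, ".scale"))
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path, pixelSize = 160, frameInterval = 2) {
  fr <- tiff::readTIFF(path, all = TRUE)
  sclPath <- paste0(path, ".scale")
  scl <- if (file.exists(sclPath)) as.numeric(readLines(sclPath))
         else rep(1, length(fr))
  frames <- mapply(function(f, s) f * s, fr, scl, SIMPLIFY = FALSE)
  Movie(frames, pixelSize = pixelSize, frameInterval = frameInterval)
}

#' Smooth and zero-base an image
#'
#' 3x3 boxcar smoothing followed by subtraction of a background estimate
#' (the frame median) with negative values clamped to zero. Both the
#' kernel and the background estimator are deliberately simple defaults;
#' pass a different `background` to override.
#'
#' @param image numeric matrix.
#' @param background background level; default `median(image)` after
#'   smoothing.
#' @return zero-based matrix of the same shape.
#' @export
preprocessFrame <- function(image, background = NULL) {
  sm <- .boxcar3(image)
  if (is.null(background)) background <- stats::median(sm)
  out <- sm - background
  out[out < 0] <- 0
  out
}

# 3x3 boxcar mean with zero padding outside the frame
.boxcar3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  acc <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + p[di + seq_len(nr), dj + seq_len(nc)]
  acc / 9
}

#' Detect intensity peaks
#'
#' Pixels strictly greater than all 8 neighbors and at least `threshold`;
#' peaks closer than `mergeRadius` pixels are merged keeping the
#' brighter.
#'
#' @param image preprocessed (zero-based) matrix.
#' @param threshold minimum peak intensity (user-set; it should sit above
#'   the background noise but below real spot maxima).
#' @param mergeRadius merge distance in pixels (default 4).
#' @return data.frame with columns row, col (1-based pixel indices) and
#'   intensity, ordered by decreasing intensity.
#' @export
detectPeaks <- function(image, threshold, mergeRadius = 4) {
  nr <- nrow(image); nc <- ncol(image)
  p <- matrix(-Inf, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- image
  ctr <- p[2:(nr + 1), 2:(nc + 1)]
  isMax <- ctr >= threshold
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    isMax <- isMax & ctr > p[di + seq_len(nr), dj + seq_len(nc)]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = integer(0), col = integer(0),
                      intensity = numeric(0)))
  pk <- data.frame(row = idx[, 1], col = idx[, 2],
                   intensity = image[idx])
  pk <- pk[order(-pk$intensity), , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      j <- (i + 1):nrow(pk)
      d2 <- (pk$row[j] - pk$row[i])^2 + (pk$col[j] - pk$col[i])^2
      keep[j][d2 < mergeRadius^2] <- FALSE
    }
  }
  rownames(pk) <- NULL
  pk[keep, , drop = FALSE]
}

#' Centroid localization in a square window
#'
#' Intensity-weighted centroid over a `window x window` (default 7x7)
#' square of the zero-based image centred on the peak pixel. Pixel
#' centres sit at 0-based integer indices; coordinates are converted to
#' micrometres at this boundary (x runs along columns, y along rows).
#'
#' @param image zero-based matrix.
#' @param peak list/row with `row`, `col` (1-based pixel indices).
#' @param window odd window size; peaks whose window exceeds the frame
#'   are rejected with an error (callers drop them with a warning).
#' @param pixelSize nm per pixel.
#' @param frame frame index stored in the localization.
#' @return data.frame row: frame, x_um, y_um, intensity.
#' @export
centroidLocalize <- function(image, peak, window = 7L, pixelSize = 160,
                             frame = 0L) {
  h <- (window - 1L) %/% 2L
  r0 <- peak$row - h; r1 <- peak$row + h
  c0 <- peak$col - h; c1 <- peak$col + h
  if (r0 < 1 || c0 < 1 || r1 > nrow(image) || c1 > ncol(image))
    stop("centroidLocalize: window outside frame")
  w <- image[r0:r1, c0:c1]
  tot <- sum(w)
  if (tot <= 0) stop("centroidLocalize: zero total intensity in window")
  rows <- (r0:r1) - 1L; cols <- (c0:c1) - 1L  # 0-based pixel centres
  cy <- sum(rowSums(w) * rows) / tot
  cx <- sum(colSums(w) * cols) / tot
  data.frame(frame = frame, x_um = cx * pixelSize * 1e-3,
             y_um = cy * pixelSize * 1e-3, intensity = tot)
}

#' Localize all spots in a movie
#'
#' preprocess -> detect -> centroid per frame; edge peaks whose 7x7
#' window leaves the frame are dropped with a warning.
#'
#' @param movie a [Movie-class].
#' @param threshold peak detection threshold (on the zero-based image).
#' @param window centroid window (odd).
#' @return data.frame frame, x_um, y_um, intensity.
#' @export
localizeMovie <- function(movie, threshold, window = 7L) {
  out <- vector("list", length(movie@frames))
  dropped <- 0L
  for (k in seq_along(movie@frames)) {
    z <- preprocessFrame(movie@frames[[k]])
    pk <- detectPeaks(z, threshold)
    locs <- list()
    for (i in seq_len(nrow(pk))) {
      loc <- tryCatch(centroidLocalize(z, pk[i, ], window = window,
                                       pixelSize = movie@pixelSize,
                                       frame = k - 1L),
                      error = function(e) NULL)
      if (is.null(loc)) dropped <- dropped + 1L else locs[[length(locs) + 1L]] <- loc
    }
    out[[k]] <- if (length(locs)) do.call(rbind, locs) else NULL
  }
  if (dropped > 0) warning("localizeMovie: dropped ", dropped, " edge peaks")
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(frame = integer(0), x_um = numeric(0),
                               y_um = numeric(0), intensity = numeric(0))
  else res
}

# all maximal partial matchings between two point sets within maxDisp,
# minimizing total squared displacement among maximum-cardinality
# matchings; exact enumeration (spot counts are 0-2 per frame in sparse
# photoactivation movies). Ties prefer the assignment pairing lower
# track indices (older trajectories) first.
.matchFrames <- function(px, py, cx, cy, maxDisp) {
  nP <- length(px); nC <- length(cx)
  if (nP == 0 || nC == 0) return(integer(nC))
  cost <- outer(px, cx, "-")^2 + outer(py, cy, "-")^2
  feas <- cost <= maxDisp^2
  best <- NULL
  assignC <- integer(nC)  # candidate -> previous index (0 = none)
  recurse <- function(ci, usedP, nMatch, totCost, assign) {
    if (ci > nC) {
      if (is.null(best) || nMatch > best$n ||
          (nMatch == best$n && totCost < best$cost - 1e-15)) {
        best <<- list(n = nMatch, cost = totCost, assign = assign)
      }
      return()
    }
    # try unmatched first so matched solutions overwrite only when better
    recurse(ci + 1L, usedP, nMatch, totCost, assign)
    for (pi in seq_len(nP)) {
      if (usedP[pi] || !feas[pi, ci]) next
      usedP[pi] <- TRUE
      assign[ci] <- pi
      recurse(ci + 1L, usedP, nMatch + 1L, totCost + cost[pi, ci], assign)
      usedP[pi] <- FALSE
      assign[ci] <- 0L
    }
  }
  if (nP * nC <= 64) {
    recurse(1L, logical(nP), 0L, 0, assignC)
    best$assign
  } else {
    # greedy fallback for dense frames: ascending cost with conflict
    # resolution
    ord <- order(cost)
    usedP <- logical(nP); usedC <- logical(nC)
    for (k in ord) {
      pi <- (k - 1L) %% nP + 1L
      ci <- (k - 1L) %/% nP + 1L
      if (!feas[pi, ci] || usedP[pi] || usedC[ci]) next
      assignC[ci] <- pi
      usedP[pi] <- TRUE; usedC[ci] <- TRUE
    }
    assignC
  }
}

#' Link localizations into trajectories
#'
#' Frame-to-frame assignment minimizing total squared displacement among
#' candidate pairs within `maxDisp` (maximum-cardinality, minimum-cost
#' matching; exact for sparse frames). Unmatched localizations start new
#' trajectories; with `memory = 0` a trajectory ends at its first missed
#' frame.
#'
#' @param locs data.frame with columns frame, x_um, y_um (sorted or not).
#' @param maxDisp maximum frame-to-frame displacement, um.
#' @param memory gap-closing frames (only 0 is supported).
#' @param frameInterval ms.
#' @param cellId cell id stored in the output records.
#' @return a [TrajectorySet-class].
#' @export
linkLocalizations <- function(locs, maxDisp, memory = 0L,
                              frameInterval = 2, cellId = "cell1") {
  stopifnot(memory == 0L)
  locs <- locs[order(locs$frame, locs$x_um, locs$y_um), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  nextId <- 1L
  out <- list()
  prev <- NULL  # data.frame x, y, traj
  lastFrame <- NULL
  for (f in frames) {
    cur <- locs[locs$frame == f, , drop = FALSE]
    ids <- integer(nrow(cur))
    if (!is.null(prev) && f == lastFrame + 1L) {
      asg <- .matchFrames(prev$x, prev$y, cur$x_um, cur$y_um, maxDisp)
      for (i in seq_len(nrow(cur))) {
        if (asg[i] > 0L) ids[i] <- prev$traj[asg[i]]
      }
    }
    for (i in seq_len(nrow(cur))) {
      if (ids[i] == 0L) { ids[i] <- nextId; nextId <- nextId + 1L }
    }
    out[[length(out) + 1L]] <- data.frame(
      cell_id = cellId, traj_id = ids, frame = f,
      x = cur$x_um, y = cur$y_um)
    prev <- data.frame(x = cur$x_um, y = cur$y_um, traj = ids)
    lastFrame <- f
  }
  rec <- if (length(out)) do.call(rbind, out)
         else data.frame(cell_id = character(0), traj_id = integer(0),
                         frame = integer(0), x = numeric(0), y = numeric(0))
  new("TrajectorySet", records = rec[order(rec$traj_id, rec$frame), ,
                                     drop = FALSE],
      frameInterval = frameInterval)
}

#' Render a synthetic single-molecule movie
#'
#' Emitters follow simulated two-state walkers; each frame accumulates a
#' 2D Gaussian PSF at every Brownian substep position within the exposure
#' (motion blur), photons split equally over substeps, on a uniform
#' background. Poisson shot noise is applied; EMCCD gain-register excess
#' noise can be approximated by `excessNoise = 2` (amplified Poisson).
#' The cell is centred in the field of view.
#'
#' @param model a [TwoStateModel-class].
#' @param config a [SimConfig-class]; `nFrames` frames are rendered.
#' @param nEmitters number of simultaneously active emitters.
#' @param psfSigma PSF standard deviation, nm.
#' @param photonsPerFrame expected photons per emitter per frame.
#' @param background expected background photons per pixel per frame.
#' @param seed integer seed.
#' @param nPixels field of view size (square), pixels.
#' @param pixelSize nm per pixel.
#' @param noise apply Poisson noise.
#' @param excessNoise variance inflation factor (1 = pure Poisson).
#' @return list: `movie` ([Movie-class]) and `truth` (a
#'   [TrajectorySet-class] of the noiseless mean emitter positions per
#'   frame, in field-of-view micrometre coordinates).
#' @export
renderMovie <- function(model, config, nEmitters = 1L, psfSigma = 120,
                        photonsPerFrame = 5000, background = 2, seed = 1L,
                        nPixels = 128L, pixelSize = 160, noise = TRUE,
                        excessNoise = 1) {
  nF <- config@nFrames
  nSub <- config@substepsPerFrame
  pxUm <- pixelSize * 1e-3
  fovUm <- nPixels * pxUm
  offset <- fovUm / 2  # cell centre -> field centre
  sigUm <- psfSigma * 1e-3
  frames <- lapply(seq_len(nF), function(k) matrix(0, nPixels, nPixels))
  truth <- list()
  for (e in seq_len(nEmitters)) {
    tr <- simulateTrajectory(model, config, seed = seed * 100L + e)
    hid <- tr$hidden
    for (k in seq_len(nF)) {
      rows <- ((k - 1L) * nSub + 1L):(k * nSub)
      xs <- hid[rows, "x"] + offset
      ys <- hid[rows, "y"] + offset
      frames[[k]] <- frames[[k]] +
        .renderSpots(xs, ys, photonsPerFrame / nSub, sigUm, nPixels, pxUm)
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = "fov", traj_id = e, frame = k - 1L,
        x = mean(xs), y = mean(ys))
    }
  }
  frames <- lapply(frames, function(f) f + background)
  if (noise) {
    frames <- withSeed(seed, lapply(frames, function(f) {
      if (excessNoise > 1) {
        excessNoise * matrix(stats::rpois(length(f), f / excessNoise),
                             nrow(f))
      } else {
        matrix(stats::rpois(length(f), f), nrow(f))
      }
    }))
  }
  truthRec <- do.call(rbind, truth)
  truthRec <- truthRec[order(truthRec$traj_id, truthRec$frame), ]
  list(movie = Movie(frames, pixelSize = pixelSize,
                     frameInterval = config@frameInterval),
       truth = new("TrajectorySet", records = truthRec,
                   frameInterval = config@frameInterval))
}

# accumulate integrated-Gaussian PSFs at positions (xs, ys) um; x runs
# along columns, y along rows; pixel centres at 0-based integer indices
# times pixelSize (the localization convention), so pixel i spans
# [(i - 0.5) px, (i + 0.5) px)
.renderSpots <- function(xs, ys, photonsEach, sigUm, nPixels, pxUm) {
  img <- matrix(0, nPixels, nPixels)
  half <- ceiling(4 * sigUm / pxUm)
  for (i in seq_along(xs)) {
    cx <- xs[i] / pxUm; cy <- ys[i] / pxUm  # in pixel units
    c0 <- max(0L, floor(cx) - half); c1 <- min(nPixels - 1L, floor(cx) + half)
    r0 <- max(0L, floor(cy) - half); r1 <- min(nPixels - 1L, floor(cy) + half)
    if (c0 > c1 || r0 > r1) next
    colsEdges <- ((c0:(c1 + 1L)) - 0.5) * pxUm
    rowsEdges <- ((r0:(r1 + 1L)) - 0.5) * pxUm
    fx <- diff(stats::pnorm(colsEdges, mean = xs[i], sd = sigUm))
    fy <- diff(stats::pnorm(rowsEdges, mean = ys[i], sd = sigUm))
    img[(r0:r1) + 1L, (c0:c1) + 1L] <-
      img[(r0:r1) + 1L, (c0:c1) + 1L] + photonsEach * outer(fy, fx)
  }
  img
}
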