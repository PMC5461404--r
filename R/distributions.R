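#' Bin displacement values into a normalized distribution
#'
#' Fixed-width bins on [0, rMax); values at or beyond rMax accumulate in
#' the last bin so that counts are conserved. Default bin width is 25 nm:
#' with a ~60 nm localization error, finer bins are noise-dominated.
#'
#' @param values non-negative displacements, um.
#' @param binWidth bin width, um.
#' @param rMax upper edge of the histogram, um.
#' @param kind "single_step" or "six_step_mean".
#' @return a [DisplacementDistribution-class].
#' @export
displacementPdf <- function(values, binWidth = 0.025, rMax = 1.2,
                            kind = c("single_step", "six_step_mean")) {
  kind <- match.arg(kind)
  if (length(values) == 0) stop("displacementPdf: empty input")
  if (any(values < 0)) stop("displacementPdf: negative displacement")
  edges <- seq(0, rMax, by = binWidth)
  if (abs(edges[length(edges)] - rMax) > 1e-12) edges <- c(edges, rMax)
  idx <- pmin(findInterval(values, edges, left.open = FALSE),
              length(edges) - 1L)
  idx[idx < 1L] <- 1L
  cnt <- tabulate(idx, nbins = length(edges) - 1L)
  new("DisplacementDistribution", binEdges = edges, counts = as.numeric(cnt),
      nTotal = length(values), kind = kind)
}

#' @rdname displacementPdf
#' @param x a `DisplacementDistribution`.
#' @export
setMethod("binEdges", "DisplacementDistribution", function(x) x@binEdges)
#' @rdname displacementPdf
#' @export
setMethod("binCenters", "DisplacementDistribution", function(x)
  (x@binEdges[-1] + x@binEdges[-length(x@binEdges)]) / 2)
#' @rdname displacementPdf
#' @export
setMethod("probability", "DisplacementDistribution", function(x)
  x@counts / x@nTotal)
#' @rdname displacementPdf
#' @export
setMethod("binCounts", "DisplacementDistribution", function(x) x@counts)

setMethod("show", "DisplacementDistribution", function(object) {
  cat(sprintf("DisplacementDistribution (%s): %d bins on [0, %g] um, n = %g\n",
              object@kind, length(object@counts),
              object@binEdges[length(object@binEdges)], object@nTotal))
})

#' Mean square displacement curve
#'
#' MSD(tau = k dt) is the mean over all within-trajectory frame pairs
#' separated by k frames of the squared 2D displacement. By default
#' trajectories are truncated to their first 7 frames (6 steps) so every
#' trajectory contributes equally, as in the six-step analyses; error
#' bars are the standard error of the mean of the squared displacements
#' per lag (a population-SD alternative is exposed via `errorType`).
#'
#' @param ts a length-filtered [TrajectorySet-class].
#' @param maxLag maximum lag in frames.
#' @param truncate truncate trajectories to maxLag + 1 frames.
#' @param errorType "sem" or "sd".
#' @return an [MSDCurve-class].
#' @export
msdCurve <- function(ts, maxLag = 6L, truncate = TRUE,
                     errorType = c("sem", "sd")) {
  errorType <- match.arg(errorType)
  r <- .orderedRecords(ts)
  if (truncate) {
    idx <- stats::ave(seq_len(nrow(r)), r$traj_id, FUN = seq_along)
    r <- r[idx <= maxLag + 1L, , drop = FALSE]
  }
  lag <- seq_len(maxLag) * ts@frameInterval
  msd <- sem <- numeric(maxLag)
  np <- integer(maxLag)
  n <- nrow(r)
  for (k in seq_len(maxLag)) {
    if (n <= k) { msd[k] <- NA; next }
    i1 <- seq_len(n - k); i2 <- i1 + k
    ok <- r$traj_id[i1] == r$traj_id[i2] & (r$frame[i2] - r$frame[i1]) == k
    sq <- (r$x[i2] - r$x[i1])^2 + (r$y[i2] - r$y[i1])^2
    sq <- sq[ok]
    np[k] <- length(sq)
    msd[k] <- mean(sq)
    s <- stats::sd(sq)
    sem[k] <- if (errorType == "sem") s / sqrt(length(sq)) else s
  }
  new("MSDCurve", lag = lag, msd = msd, sem = sem, nPairs = np)
}

setMethod("show", "MSDCurve", function(object) {
  cat("MSDCurve:\n")
  print(data.frame(lag_ms = object@lag, msd_um2 = object@msd,
                   sem = object@sem, n = object@nPairs))
})

#' Diffusion coefficient and localization error from an MSD curve
#'
#' Fits the line through the first two MSD points: MSD = 4 D tau +
#' 4 sigma^2, so D = slope/4 and sigma = sqrt(intercept/4). A negative
#' intercept is reported as sigma = 0 with `sigmaClamped = TRUE`.
#'
#' @param curve an [MSDCurve-class] with at least two lags.
#' @return list with `D` (um^2/s), `sigma` (nm), `sigmaClamped`.
#' @examples
#' # slope 0.008 um^2/ms -> D = 2 um^2/s; intercept 0.002 -> sigma = 22.4 nm
#' @export
dSigmaFromMsd <- function(curve) {
  stopifnot(length(curve@lag) >= 2)
  slope <- (curve@msd[2] - curve@msd[1]) / (curve@lag[2] - curve@lag[1])
  intercept <- curve@msd[1] - slope * curve@lag[1]
  D <- slope * 1000 / 4   # um^2/ms -> um^2/s
  clamped <- intercept < 0
  sigma <- sqrt(max(intercept, 0) / 4) * 1000  # um -> nm
  list(D = D, sigma = sigma, sigmaClamped = clamped)
}

#' Select slowest/fastest trajectories by stepwise diffusion estimate
#'
#' Computes per trajectory the mean of the six one-step diffusion
#' estimates <D>_6 = mean(r_i^2 / (4 dt)) and returns the slowest and
#' fastest `quantile` subsets with the cutoff D values. Ties are broken
#' by trajectory id order (stable).
#'
#' @param ts a [TrajectorySet-class] of six-step trajectories.
#' @param quantile fraction selected at each extreme (default 0.10).
#' @return list with `slow` and `fast` [TrajectorySet-class] subsets,
#'   `cutoffs` (named c(slow, fast), um^2/s) and the per-trajectory
#'   estimates `D6` (named by traj_id).
#' @export
stepwiseDSelection <- function(ts, quantile = 0.10) {
  st <- .stepTable(ts)
  idx <- stats::ave(seq_along(st$r), st$traj_id, FUN = seq_along)
  st <- st[idx <= 6, , drop = FALSE]
  dt_s <- ts@frameInterval * 1e-3
  ids <- unique(st$traj_id)
  D6 <- as.numeric(tapply(st$r^2 / (4 * dt_s),
                          factor(st$traj_id, levels = ids), mean))
  names(D6) <- as.character(ids)
  nSel <- max(1L, floor(length(D6) * quantile))
  ord <- order(D6, seq_along(D6))  # stable: ties by traj order
  slowIds <- names(D6)[ord[seq_len(nSel)]]
  fastIds <- names(D6)[rev(ord)[seq_len(nSel)]]
  subsetTs <- function(ids) new("TrajectorySet",
    records = ts@records[as.character(ts@records$traj_id) %in% ids, ,
                         drop = FALSE],
    frameInterval = ts@frameInterval)
  list(slow = subsetTs(slowIds), fast = subsetTs(fastIds),
       cutoffs = c(slow = unname(D6[slowIds[length(slowIds)]]),
                   fast = unname(D6[fastIds[length(fastIds)]])),
       D6 = D6)
}
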