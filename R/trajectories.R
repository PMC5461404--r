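#' Construct a trajectory set
#'
#' @param records data.frame with columns cell_id, traj_id, frame, x, y
#'   (um) and optionally state.
#' @param frameInterval camera frame interval, ms.
#' @return a [TrajectorySet-class].
#' @export
TrajectorySet <- function(records, frameInterval = 2) {
  new("TrajectorySet", records = as.data.frame(records),
      frameInterval = frameInterval)
}

#' @rdname TrajectorySet
#' @param x a `TrajectorySet`.
#' @export
setMethod("records", "TrajectorySet", function(x) x@records)
#' @rdname TrajectorySet
#' @export
setMethod("frameInterval", "TrajectorySet", function(x) x@frameInterval)
#' @rdname TrajectorySet
#' @export
setMethod("nTrajectories", "TrajectorySet", function(x)
  length(unique(x@records$traj_id)))

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet: %d trajectories, %d localizations, dt = %g ms\n",
              nTrajectories(object), nrow(object@records),
              object@frameInterval))
})

# records ordered by (traj_id, frame); most operations assume this
.orderedRecords <- function(ts) {
  r <- ts@records
  r[order(r$traj_id, r$frame), , drop = FALSE]
}

#' Drop trajectories shorter than a minimum number of frames
#'
#' A trajectory of at least 7 localizations yields at least six single
#' steps, the unit of the six-step analyses.
#'
#' @param ts a [TrajectorySet-class].
#' @param minFrames minimum localizations per trajectory (default 7).
#' @param verbose message the number of dropped trajectories.
#' @return the filtered [TrajectorySet-class].
#' @export
filterByLength <- function(ts, minFrames = 7L, verbose = FALSE) {
  r <- ts@records
  len <- table(r$traj_id)
  keep <- names(len)[len >= minFrames]
  dropped <- length(len) - length(keep)
  if (verbose) message("filterByLength: dropped ", dropped, " of ",
                       length(len), " trajectories")
  new("TrajectorySet", records = r[as.character(r$traj_id) %in% keep, ,
                                   drop = FALSE],
      frameInterval = ts@frameInterval)
}

# steps (r, traj_id) between consecutive frames, ordered by traj then frame
.stepTable <- function(ts) {
  r <- .orderedRecords(ts)
  if (nrow(r) < 2) return(data.frame(traj_id = r$traj_id[0], r = numeric(0)))
  n <- nrow(r)
  same <- r$traj_id[-1] == r$traj_id[-n]
  dr <- sqrt(diff(r$x)^2 + diff(r$y)^2)
  data.frame(traj_id = r$traj_id[-1][same], r = dr[same])
}

#' Pooled single-step displacement magnitudes
#'
#' r = sqrt(dx^2 + dy^2) for every pair of consecutive frames within each
#' trajectory; a trajectory of n localizations contributes n - 1 steps.
#'
#' @param ts a length-filtered [TrajectorySet-class].
#' @return numeric vector of displacements, um.
#' @export
singleStepDisplacements <- function(ts) .stepTable(ts)$r

#' Per-trajectory mean of the first six single-step displacements
#'
#' Each trajectory of at least 7 frames contributes one value, the mean
#' of its first six steps; longer trajectories are truncated to six
#' steps. Trajectories with fewer than six steps are skipped with a
#' warning.
#'
#' @param ts a [TrajectorySet-class].
#' @return numeric vector of <r>_6 values, um, one per trajectory in
#'   traj_id order.
#' @export
meanSixStep <- function(ts) {
  st <- .stepTable(ts)
  if (nrow(st) == 0) return(numeric(0))
  idx <- stats::ave(seq_along(st$r), st$traj_id, FUN = seq_along)
  nsteps <- table(st$traj_id)
  short <- sum(nsteps < 6)
  if (short > 0)
    warning("meanSixStep: skipped ", short, " trajectories with < 6 steps")
  keepIds <- names(nsteps)[nsteps >= 6]
  sel <- st[idx <= 6 & as.character(st$traj_id) %in% keepIds, , drop = FALSE]
  as.numeric(tapply(sel$r, factor(sel$traj_id, levels = unique(sel$traj_id)),
                    mean))
}

#' Pooled scaled axial distribution
#'
#' Scales each localization's axial coordinate by its cell's tip-to-tip
#' length (cells may first be restricted to a 1-um length window via
#' `lengthRange`) and bins the pooled scaled positions on [-0.5, 0.5].
#' Localizations falling outside the nominal cell (|x| > L/2, possible
#' for experimental data due to localization error) are rejected with a
#' warning count rather than clipped.
#'
#' @param ts a [TrajectorySet-class] with cell-frame coordinates.
#' @param cells data.frame with columns cell_id, length_um.
#' @param nBins number of axial bins.
#' @param lengthRange optional c(min, max) cell length window, um.
#' @return an [AxialProfile-class].
#' @export
axialDistribution <- function(ts, cells, nBins = 40L, lengthRange = NULL) {
  r <- ts@records
  len <- cells$length_um[match(r$cell_id, cells$cell_id)]
  if (anyNA(len)) stop("axialDistribution: cell_id missing from cells table")
  if (!is.null(lengthRange)) {
    keep <- len >= lengthRange[1] & len < lengthRange[2]
    r <- r[keep, , drop = FALSE]; len <- len[keep]
  }
  out <- abs(r$x) > len / 2 + 1e-12
  if (any(out)) {
    warning("axialDistribution: rejected ", sum(out),
            " localizations outside the nominal cell")
    r <- r[!out, , drop = FALSE]; len <- len[!out]
  }
  xs <- r$x / len
  edges <- seq(-0.5, 0.5, length.out = nBins + 1L)
  cnt <- graphics::hist(xs, breaks = edges, plot = FALSE)$counts
  new("AxialProfile", binEdges = edges, probability = cnt / sum(cnt))
}
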