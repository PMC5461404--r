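#' Sample a two-state path of exponential dwell intervals
#'
#' The initial state is drawn from the stationary distribution
#' P(bound) = tauBound/(tauBound + tauFree); dwell times are i.i.d.
#' exponential with the current state's mean.
#'
#' @param tauFree,tauBound mean dwell times in ms (> 0). `tauBound = Inf`
#'   disables exchange (single interval in the free state and vice versa).
#' @param duration total path duration, ms.
#' @param seed integer seed.
#' @return data.frame with columns start, end (ms) and state
#'   ("bound"/"free"), contiguous and covering [0, duration].
#' @export
sampleStatePath <- function(tauFree, tauBound, duration, seed) {
  stopifnot(tauFree > 0, tauBound > 0, duration > 0)
  withSeed(seed, {
    # an infinite lifetime disables exchange: one interval at the
    # stationary state (tauBound -> Inf pins the molecule bound)
    if (is.infinite(tauBound) || is.infinite(tauFree)) {
      state <- if (is.infinite(tauBound) && !is.infinite(tauFree))
        "bound" else "free"
      return(data.frame(start = 0, end = duration, state = state))
    }
    pBound <- tauBound / (tauBound + tauFree)
    state <- if (runif(1) < pBound) "bound" else "free"
    starts <- numeric(0); ends <- numeric(0); states <- character(0)
    t <- 0
    while (t < duration) {
      mean_dwell <- if (state == "bound") tauBound else tauFree
      dwell <- rexp(1, 1 / mean_dwell)
      t2 <- min(t + dwell, duration)
      starts <- c(starts, t); ends <- c(ends, t2); states <- c(states, state)
      t <- t2
      state <- if (state == "bound") "free" else "bound"
    }
    data.frame(start = starts, end = ends, state = states)
  })
}

# Low-level bridge to the compiled ensemble simulator.
.simulateRaw <- function(model, config, nTraj, seed,
                         fixedState = NULL, initX = NULL, initState = NULL,
                         static = FALSE, returnHidden = FALSE) {
  stopifnot(is(model, "TwoStateModel"), is(config, "SimConfig"))
  cell <- config@cell
  exchange <- model@exchange && !static
  if (is.null(fixedState)) {
    fixedState <- rep.int(-1L, nTraj)
  } else {
    stopifnot(length(fixedState) == nTraj)
    fixedState <- as.integer(fixedState)
  }
  if (is.null(initX)) initX <- rep.int(NA_real_, nTraj)
  if (is.null(initState)) initState <- rep.int(-1L, nTraj)
  .simEnsembleCpp(
    n_traj = as.integer(nTraj), n_frames = config@nFrames,
    frame_interval = config@frameInterval, exposure = config@exposure,
    n_sub = config@substepsPerFrame,
    total_length = totalLength(cell), diameter = cellDiameter(cell),
    D_slow = model@Dslow, D_fast = model@Dfast, f_slow = model@fSlow,
    tau_free = if (exchange) model@tauFree else 1,
    tau_bound = if (exchange) model@tauBound else 1,
    sigma_slow = model@sigmaSlow * 1e-3,
    sigma_fast = model@sigmaFast * 1e-3,
    exchange = exchange, blur = config@blur, confine = config@confine,
    max_redraws = 1000L, seed = as.numeric(seed),
    init_x = as.numeric(initX), fixed_state = fixedState,
    init_state = as.integer(initState), return_hidden = returnHidden)
}

#' Simulate a single two-state trajectory
#'
#' One molecule diffusing inside the configured spherocylinder, switching
#' between bound (Dslow) and free (Dfast) states with exponential dwell
#' times, observed at the camera frame interval. Observed positions are
#' the (x, y) projection of the motion-blur average (if `blur`) plus
#' i.i.d. Gaussian noise with the per-coordinate sigma of the frame's
#' majority-occupancy state. The hidden 3D substep path and per-frame
#' majority states are returned alongside.
#'
#' @param model a [TwoStateModel-class].
#' @param config a [SimConfig-class].
#' @param seed integer seed (trajectory stream is counter-based).
#' @return list with elements `observed` (data.frame frame, x, y, state)
#'   and `hidden` (matrix of per-substep x, y, z, state).
#' @export
simulateTrajectory <- function(model, config, seed) {
  raw <- .simulateRaw(model, config, 1L, seed, returnHidden = TRUE)
  hid <- raw$hidden[[1]]
  colnames(hid) <- c("x", "y", "z", "state")
  list(observed = data.frame(frame = seq_len(config@nFrames) - 1L,
                             x = raw$x[, 1], y = raw$y[, 1],
                             state = raw$state[, 1]),
       hidden = hid)
}

#' Simulate an ensemble of two-state trajectories
#'
#' Independent trajectories with per-trajectory counter-based seed
#' streams derived from `seed`, so the ensemble is reproducible and
#' order-independent. With `static = TRUE`, exchange is disabled and each
#' trajectory's single state is drawn Bernoulli(fSlow) (or taken from
#' `fixedState`).
#'
#' @param model a [TwoStateModel-class].
#' @param config a [SimConfig-class].
#' @param nTraj number of trajectories (>= 1).
#' @param seed master integer seed.
#' @param static disable exchange; single state per trajectory.
#' @param fixedState optional per-trajectory state (1 = bound, 0 = free,
#'   -1 = draw), overriding the Bernoulli/stationary draw.
#' @param initX optional per-trajectory initial axial position (um, cell
#'   frame); NA entries are drawn uniformly over the cell volume.
#' @param initState optional per-trajectory initial state (1/0/-1); with
#'   exchange on, only the starting state is forced and kinetics proceed.
#' @param cellIds optional per-trajectory cell identifier.
#' @return a [TrajectorySet-class]; the records carry a `state` column
#'   with the per-frame majority hidden state.
#' @export
simulateEnsemble <- function(model, config, nTraj, seed, static = FALSE,
                             fixedState = NULL, initX = NULL,
                             initState = NULL, cellIds = NULL) {
  stopifnot(nTraj >= 1)
  raw <- .simulateRaw(model, config, nTraj, seed, fixedState = fixedState,
                      initX = initX, initState = initState, static = static)
  nF <- config@nFrames
  if (is.null(cellIds)) cellIds <- rep.int("cell1", nTraj)
  rec <- data.frame(
    cell_id = rep(cellIds, each = nF),
    traj_id = rep(seq_len(nTraj), each = nF),
    frame = rep.int(seq_len(nF) - 1L, nTraj),
    x = as.vector(raw$x), y = as.vector(raw$y),
    state = as.vector(raw$state))
  new("TrajectorySet", records = rec, frameInterval = config@frameInterval)
}
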