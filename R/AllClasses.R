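#' @import methods
NULL

#' Spherocylindrical cell geometry
#'
#' A rod-shaped bacterial cell idealized as a cylinder of diameter `d`
#' capped by two hemispheres, with tip-to-tip length `L`. The derived
#' cylinder half-length is `a = (L - d)/2` and the cap radius `r_c = d/2`.
#'
#' @slot totalLength tip-to-tip length L in micrometres.
#' @slot diameter cell diameter d in micrometres.
#' @export
setClass("Spherocylinder",
  representation(totalLength = "numeric", diameter = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@totalLength) != 1L || length(object@diameter) != 1L)
      msg <- c(msg, "totalLength and diameter must be scalars")
    else {
      if (!is.finite(object@diameter) || object@diameter <= 0)
        msg <- c(msg, "diameter must be > 0")
      if (!is.finite(object@totalLength) || object@totalLength < object@diameter)
        msg <- c(msg, "totalLength must be >= diameter")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Two-state diffusion/kinetics model
#'
#' Parameterization of a molecule that switches between a ribosome-bound,
#' slowly diffusing state (`Dslow`) and a free, rapidly diffusing state
#' (`Dfast`), with exponential dwell times `tauBound` and `tauFree`.
#' When exchange is enabled the stationary bound fraction is tied to the
#' lifetimes: `fSlow = tauBound/(tauBound + tauFree)`.
#'
#' @slot Dslow,Dfast diffusion coefficients, um^2/s.
#' @slot fSlow stationary fraction in the slow (bound) state.
#' @slot tauFree,tauBound mean dwell times in ms (NA when exchange is off).
#' @slot sigmaSlow,sigmaFast per-coordinate dynamic localization error, nm.
#' @slot exchange logical; whether binding/unbinding kinetics are active.
#' @export
setClass("TwoStateModel",
  representation(Dslow = "numeric", Dfast = "numeric", fSlow = "numeric",
                 tauFree = "numeric", tauBound = "numeric",
                 sigmaSlow = "numeric", sigmaFast = "numeric",
                 exchange = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@Dslow < 0) msg <- c(msg, "Dslow must be >= 0")
    if (object@Dfast < object@Dslow) msg <- c(msg, "Dfast must be >= Dslow")
    if (object@fSlow < 0 || object@fSlow > 1)
      msg <- c(msg, "fSlow must be in [0, 1]")
    if (object@sigmaSlow < 0 || object@sigmaFast < 0)
      msg <- c(msg, "sigma values must be >= 0")
    if (object@exchange) {
      if (!is.finite(object@tauFree) || !is.finite(object@tauBound) ||
          object@tauFree <= 0 || object@tauBound <= 0)
        msg <- c(msg, "tauFree and tauBound must be > 0 when exchange is enabled")
      else {
        f <- object@tauBound / (object@tauBound + object@tauFree)
        if (abs(f - object@fSlow) > 1e-9)
          msg <- c(msg, "fSlow inconsistent with tauBound/(tauBound + tauFree)")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Simulation configuration
#'
#' Imaging/integration settings for the forward simulator: camera frame
#' interval and exposure (ms), Brownian substeps per frame, number of
#' frames per trajectory, the confining cell, and whether observed
#' positions are motion-blur averages of the substep positions.
#'
#' @slot frameInterval,exposure ms; continuous illumination means
#'   `exposure == frameInterval`.
#' @slot substepsPerFrame Brownian substeps spanning the exposure.
#' @slot nFrames frames per trajectory.
#' @slot cell a [Spherocylinder-class].
#' @slot blur logical; motion-blur averaging of substep positions.
#' @slot confine logical; confinement by rejection resampling.
#' @export
setClass("SimConfig",
  representation(frameInterval = "numeric", exposure = "numeric",
                 substepsPerFrame = "integer", nFrames = "integer",
                 cell = "Spherocylinder", blur = "logical",
                 confine = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@exposure > object@frameInterval)
      msg <- c(msg, "exposure must be <= frameInterval")
    if (object@exposure <= 0) msg <- c(msg, "exposure must be > 0")
    if (object@substepsPerFrame < 1L)
      msg <- c(msg, "substepsPerFrame must be >= 1")
    if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Set of single-particle trajectories
#'
#' Per-frame observed 2D localizations grouped into trajectories. The
#' record table has columns `cell_id`, `traj_id`, `frame`, `x`, `y` and
#' optionally `state` (simulated data only; 1 = bound). Frames within a
#' trajectory are strictly increasing and consecutive; gapped detections
#' must be split upstream.
#'
#' @slot records data.frame of localizations.
#' @slot frameInterval camera frame interval in ms.
#' @export
setClass("TrajectorySet",
  representation(records = "data.frame", frameInterval = "numeric"),
  validity = function(object) {
    req <- c("cell_id", "traj_id", "frame", "x", "y")
    if (!all(req %in% names(object@records)))
      return(paste("records must have columns", paste(req, collapse = ", ")))
    r <- object@records
    if (nrow(r) > 0) {
      o <- order(r$traj_id, r$frame)
      fr <- r$frame[o]; id <- r$traj_id[o]
      same <- id[-1] == id[-length(id)]
      if (any(same & diff(fr) != 1))
        return("frames within a trajectory must be consecutive")
    }
    TRUE
  })

#' Binned displacement distribution
#'
#' Normalized histogram of single-step displacements P(r) or of
#' per-trajectory six-step mean displacements P(<r>6), with raw counts
#' retained for Poisson error propagation.
#'
#' @slot binEdges bin edges in micrometres (length nbins + 1).
#' @slot counts per-bin counts (numeric; mixture models carry pseudo-counts).
#' @slot nTotal total number of contributing values.
#' @slot kind "single_step" or "six_step_mean".
#' @export
setClass("DisplacementDistribution",
  representation(binEdges = "numeric", counts = "numeric",
                 nTotal = "numeric", kind = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@counts) != length(object@binEdges) - 1L)
      msg <- c(msg, "counts must have length(binEdges) - 1")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    if (is.unsorted(object@binEdges, strictly = TRUE))
      msg <- c(msg, "binEdges must be strictly increasing")
    if (!object@kind %in% c("single_step", "six_step_mean"))
      msg <- c(msg, "kind must be 'single_step' or 'six_step_mean'")
    if (object@nTotal > 0 &&
        abs(sum(object@counts) / object@nTotal - 1) > 1e-9)
      msg <- c(msg, "counts must sum to nTotal")
    if (is.null(msg)) TRUE else msg
  })

#' Mean-square-displacement curve
#'
#' MSD(tau) at lags tau = k * frameInterval with standard errors and pair
#' counts per lag.
#' @slot lag lag times, ms.
#' @slot msd mean square displacement, um^2.
#' @slot sem standard error of the mean squared displacement, um^2.
#' @slot nPairs displacement pairs per lag.
#' @export
setClass("MSDCurve",
  representation(lag = "numeric", msd = "numeric", sem = "numeric",
                 nPairs = "integer"),
  validity = function(object) {
    n <- length(object@lag)
    if (length(object@msd) != n || length(object@sem) != n ||
        length(object@nPairs) != n)
      return("lag, msd, sem, nPairs must have equal length")
    if (any(object@msd < 0)) return("msd must be >= 0")
    TRUE
  })

#' Axial occupancy profile
#'
#' Probability per bin of the scaled axial coordinate in [-0.5, +0.5]
#' (0 = cell centre, +/-0.5 = cell tips).
#' @slot binEdges scaled axial bin edges, symmetric about 0.
#' @slot probability per-bin probabilities summing to 1.
#' @export
setClass("AxialProfile",
  representation(binEdges = "numeric", probability = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@probability) != length(object@binEdges) - 1L)
      msg <- c(msg, "probability must have length(binEdges) - 1")
    if (any(object@probability < -1e-12)) msg <- c(msg, "probabilities must be >= 0")
    if (abs(sum(object@probability) - 1) > 1e-9)
      msg <- c(msg, "probabilities must sum to 1")
    if (max(abs(object@binEdges + rev(object@binEdges))) > 1e-9)
      msg <- c(msg, "bins must be symmetric about 0")
    if (is.null(msg)) TRUE else msg
  })

#' Library of simulated single-state model distributions
#'
#' P_model(r; D, sigma) entries on a common binning, each built from a
#' simulated static single-state ensemble in the target cell geometry.
#' Entries are keyed "D=<D>|sigma=<sigma>".
#'
#' @slot entries named list of [DisplacementDistribution-class] objects.
#' @slot Dgrid,sigmaGrid the grids used (um^2/s; nm).
#' @slot binEdges shared bin edges, um.
#' @slot provenance list: SimConfig, nTraj, seed.
#' @export
setClass("ModelLibrary",
  representation(entries = "list", Dgrid = "numeric", sigmaGrid = "numeric",
                 binEdges = "numeric", provenance = "list"),
  validity = function(object) {
    ok <- vapply(object@entries, function(e)
      is(e, "DisplacementDistribution") &&
        isTRUE(all.equal(e@binEdges, object@binEdges)), logical(1))
    if (!all(ok)) return("all entries must share the library binEdges")
    TRUE
  })

#' Static mixture fit result
#'
#' Best fit of a one-state or static (non-exchanging) two-state mixture
#' P_model(r) = fSlow * P(r; Dslow) + (1 - fSlow) * P(r; Dfast).
#' @slot nStates 1 or 2.
#' @slot Dslow,Dfast um^2/s (one-state fits use Dfast, fSlow = 0).
#' @slot fSlow,fFast fractions summing to 1.
#' @slot sigmaSlow,sigmaFast nm (fit inputs, not free parameters by default).
#' @slot chi2nu reduced chi-square at the minimizer.
#' @slot constrained named logical: which parameters were held fixed.
#' @slot onBoundary TRUE if the minimizer sits on a grid edge.
#' @export
setClass("StaticFit",
  representation(nStates = "integer", Dslow = "numeric", Dfast = "numeric",
                 fSlow = "numeric", fFast = "numeric",
                 sigmaSlow = "numeric", sigmaFast = "numeric",
                 chi2nu = "numeric", constrained = "logical",
                 onBoundary = "logical"),
  validity = function(object) {
    msg <- NULL
    if (abs(object@fSlow + object@fFast - 1) > 1e-9)
      msg <- c(msg, "fSlow + fFast must equal 1")
    if (object@chi2nu < 0) msg <- c(msg, "chi2nu must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Reduced chi-square grid
#'
#' chi2nu evaluated over a parameter grid, used for confidence regions
#' (chi2nu <= threshold).
#' @slot axes named list of grid values per parameter.
#' @slot values array of chi2nu with dim = lengths of axes.
#' @export
setClass("ChiSqGrid",
  representation(axes = "list", values = "array"),
  validity = function(object) {
    if (!identical(unname(dim(object@values)),
                   unname(vapply(object@axes, length, integer(1)))))
      return("dim(values) must match axis lengths")
    TRUE
  })

#' Exchange-lifetime fit result
#'
#' Best-fit dwell times from matching simulated P(<r>6) distributions to
#' the data with the lifetime ratio fixed by the static populations.
#' @slot tauFree,tauBound ms.
#' @slot chi2nu reduced chi-square at the minimizer.
#' @slot fixedRatio tauFree/tauBound held during the search.
#' @export
setClass("KineticFit",
  representation(tauFree = "numeric", tauBound = "numeric",
                 chi2nu = "numeric", fixedRatio = "numeric"),
  validity = function(object) {
    if (abs(object@tauFree / object@tauBound - object@fixedRatio) > 1e-9)
      return("tauFree/tauBound must equal fixedRatio")
    TRUE
  })

#' Fluorescence movie
#'
#' A stack of 2D intensity frames with the camera pixel size and frame
#' interval.
#' @slot frames list of numeric matrices, constant dimensions.
#' @slot pixelSize nm per pixel.
#' @slot frameInterval ms.
#' @export
setClass("Movie",
  representation(frames = "list", pixelSize = "numeric",
                 frameInterval = "numeric"),
  validity = function(object) {
    if (length(object@frames) == 0) return("at least one frame required")
    d <- dim(object@frames[[1]])
    ok <- vapply(object@frames, function(f)
      is.matrix(f) && identical(dim(f), d) && all(f >= 0), logical(1))
    if (!all(ok)) return("frames must be non-negative matrices of constant shape")
    TRUE
  })
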