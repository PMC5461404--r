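#' Default logarithmic diffusion-coefficient search grid
#'
#' Log-spaced from 0.05 to 20 um^2/s at 25 points per decade.
#' @param from,to range, um^2/s.
#' @param perDecade grid density.
#' @return numeric vector of D values.
#' @export
defaultDGrid <- function(from = 0.05, to = 20, perDecade = 25) {
  n <- ceiling(log10(to / from) * perDecade) + 1L
  10^seq(log10(from), log10(to), length.out = n)
}

.libKey <- function(D, sigma) sprintf("D=%.10g|sigma=%.10g", D, sigma)

#' Build a library of simulated single-state model distributions
#'
#' For each (D, sigma) pair, a static single-state ensemble is simulated
#' in the target cell geometry and imaging configuration and binned with
#' the experimental binning; these numerical P_model(r; D, sigma) curves
#' are the fitting functions for the static mixture fits.
#'
#' @param Dgrid diffusion coefficients, um^2/s.
#' @param sigmaGrid localization errors, nm.
#' @param config a [SimConfig-class] matching the experimental imaging.
#' @param nTraj trajectories per entry (each contributes nFrames - 1
#'   steps; at least 10,000 steps per entry are required).
#' @param seed master seed; entry seeds are derived by index.
#' @param binEdges bin edges of the experimental target, um.
#' @return a [ModelLibrary-class].
#' @export
buildModelLibrary <- function(Dgrid, sigmaGrid, config, nTraj, seed,
                              binEdges) {
  stopifnot(length(Dgrid) >= 1, length(sigmaGrid) >= 1)
  if (nTraj * (config@nFrames - 1L) < 10000)
    stop("buildModelLibrary: need >= 10,000 steps per entry")
  entries <- list()
  k <- 0L
  for (sig in sigmaGrid) for (D in Dgrid) {
    k <- k + 1L
    m <- TwoStateModel(Dslow = D, Dfast = D, fSlow = 1,
                       sigmaSlow = sig, sigmaFast = sig)
    ts <- simulateEnsemble(m, config, nTraj, seed = seed + 1000L * k,
                           static = TRUE)
    r <- singleStepDisplacements(ts)
    entries[[.libKey(D, sig)]] <- .binWithEdges(r, binEdges, "single_step")
  }
  new("ModelLibrary", entries = entries, Dgrid = Dgrid,
      sigmaGrid = sigmaGrid, binEdges = binEdges,
      provenance = list(config = config, nTraj = nTraj, seed = seed))
}

# bin values onto fixed edges, overflow into last bin (counts conserved)
.binWithEdges <- function(values, edges, kind) {
  idx <- pmin(findInterval(values, edges, left.open = FALSE),
              length(edges) - 1L)
  idx[idx < 1L] <- 1L
  cnt <- tabulate(idx, nbins = length(edges) - 1L)
  new("DisplacementDistribution", binEdges = edges,
      counts = as.numeric(cnt), nTotal = length(values), kind = kind)
}

#' Fetch a library entry
#' @param library a [ModelLibrary-class].
#' @param D,sigma the entry key values.
#' @return a [DisplacementDistribution-class].
#' @export
libraryEntry <- function(library, D, sigma) {
  e <- library@entries[[.libKey(D, sigma)]]
  if (is.null(e)) stop("no library entry for D = ", D, ", sigma = ", sigma)
  e
}

setMethod("show", "ModelLibrary", function(object) {
  cat(sprintf("ModelLibrary: %d entries (%d D x %d sigma), %d bins\n",
              length(object@entries), length(object@Dgrid),
              length(object@sigmaGrid), length(object@binEdges) - 1L))
})

#' Reduced chi-square between two binned distributions
#'
#' chi^2 = sum_i (p_exp,i - p_model,i)^2 / s_i^2 where s_i^2 combines the
#' Poisson errors of both normalized histograms, evaluated with the
#' pooled proportion: s_i^2 = pbar_i (1/n_exp + 1/n_model). (Evaluating
#' the experimental term with the observed proportion instead biases the
#' statistic upward wherever a low-count bin fluctuates to zero; the
#' pooled form restores E[chi2nu] = 1 under the null.)
#' nu = n_admitted_bins - nFreeParams - 1. Runs of bins in which both
#' histograms hold fewer than 5 counts are merged into their neighbor
#' before evaluation; merged-out empty tail groups are dropped.
#'
#' @param experimental,model [DisplacementDistribution-class] objects on
#'   identical bin edges.
#' @param nFreeParams number of fitted parameters actually varied.
#' @return the reduced chi-square (scalar).
#' @export
reducedChiSquare <- function(experimental, model, nFreeParams) {
  if (!isTRUE(all.equal(experimental@binEdges, model@binEdges)))
    stop("reducedChiSquare: mismatched binning")
  res <- .chisqBinnedCpp(experimental@counts, model@counts,
                         experimental@nTotal, model@nTotal)
  nu <- res[2] - nFreeParams - 1
  if (nu <= 0) stop("reducedChiSquare: nu <= 0 (too few admitted bins)")
  res[1] / nu
}

#' Fit a static one- or two-state mixture by chi-square grid search
#'
#' Exhaustive search of the model library for the mixture
#' `f_slow P(r; D_slow, sigma_slow) + (1 - f_slow) P(r; D_fast,
#' sigma_fast)` minimizing the reduced chi-square against the data.
#' `D_slow <= D_fast` is enforced; ties are broken toward smaller D_fast,
#' then smaller f_slow. Sigma values are fit inputs (from MSD intercepts
#' or known imaging calibration), not free parameters.
#'
#' @param experimental target [DisplacementDistribution-class].
#' @param library a [ModelLibrary-class] whose sigmaGrid contains the
#'   requested sigma values.
#' @param nStates 1 or 2.
#' @param sigmaSlow,sigmaFast localization error (nm) assigned to each
#'   component (one-state fits use sigmaFast).
#' @param DslowFixed,DfastFixed,fSlowFixed optional constraints.
#' @param fStep grid step for fSlow (default 0.05).
#' @return list with `fit` ([StaticFit-class]) and `grid`
#'   ([ChiSqGrid-class]).
#' @export
fitStatic <- function(experimental, library, nStates = 2L,
                      sigmaSlow = 50, sigmaFast = 75,
                      DslowFixed = NULL, DfastFixed = NULL,
                      fSlowFixed = NULL, fStep = 0.05) {
  stopifnot(nStates %in% c(1L, 2L))
  edges <- library@binEdges
  if (!isTRUE(all.equal(experimental@binEdges, edges)))
    stop("fitStatic: target binning differs from library binning")
  Dg <- library@Dgrid
  nModel <- library@entries[[1]]@nTotal
  probFor <- function(D, sigma) probability(libraryEntry(library, D, sigma))
  # fixed-D constraints snap to the nearest library grid point (log scale)
  snap <- function(D) Dg[which.min(abs(log(Dg) - log(D)))]
  ceExp <- experimental@counts; nExp <- experimental@nTotal
  chiFast <- function(pMix, nFree) {
    res <- .chisqBinnedCpp(ceExp, pMix * nModel, nExp, nModel)
    nu <- res[2] - nFree - 1
    if (nu <= 0) return(NA_real_)
    res[1] / nu
  }

  if (nStates == 1L) {
    Ds <- if (is.null(DfastFixed)) Dg else snap(DfastFixed)
    chi <- vapply(Ds, function(D) {
      chiFast(probFor(D, sigmaFast),
              nFree = if (is.null(DfastFixed)) 1L else 0L)
    }, numeric(1))
    i <- which.min(chi)
    fit <- new("StaticFit", nStates = 1L, Dslow = NA_real_, Dfast = Ds[i],
               fSlow = 0, fFast = 1, sigmaSlow = NA_real_,
               sigmaFast = sigmaFast, chi2nu = chi[i],
               constrained = c(Dslow = FALSE, Dfast = !is.null(DfastFixed),
                               fSlow = FALSE),
               onBoundary = i == 1L || i == length(Ds))
    grid <- new("ChiSqGrid", axes = list(Dfast = Ds),
                values = array(chi, dim = length(Ds)))
    return(list(fit = fit, grid = grid))
  }

  DsGrid <- if (is.null(DslowFixed)) Dg else snap(DslowFixed)
  DfGrid <- if (is.null(DfastFixed)) Dg else snap(DfastFixed)
  fGrid <- if (is.null(fSlowFixed)) seq(0, 1, by = fStep) else fSlowFixed
  nFree <- sum(is.null(DslowFixed), is.null(DfastFixed), is.null(fSlowFixed))
  pSlowMat <- vapply(DsGrid, probFor, numeric(length(edges) - 1L),
                     sigma = sigmaSlow)
  pFastMat <- vapply(DfGrid, probFor, numeric(length(edges) - 1L),
                     sigma = sigmaFast)

  vals <- array(NA_real_, dim = c(length(DsGrid), length(DfGrid),
                                  length(fGrid)))
  best <- list(chi = Inf)
  for (jf in seq_along(DfGrid)) for (kf in seq_along(fGrid))
    for (is_ in seq_along(DsGrid)) {
      if (DsGrid[is_] > DfGrid[jf] + 1e-12) next
      pMix <- fGrid[kf] * pSlowMat[, is_] + (1 - fGrid[kf]) * pFastMat[, jf]
      chi <- chiFast(pMix, max(nFree, 1L))
      if (is.na(chi)) next
      vals[is_, jf, kf] <- chi
      if (chi < best$chi) {
        best <- list(chi = chi, Ds = DsGrid[is_], Df = DfGrid[jf],
                     f = fGrid[kf],
                     onB = is_ %in% c(1L, length(DsGrid)) && is.null(DslowFixed) ||
                       jf %in% c(1L, length(DfGrid)) && is.null(DfastFixed) ||
                       kf %in% c(1L, length(fGrid)) && is.null(fSlowFixed))
      }
    }
  if (!is.finite(best$chi)) stop("fitStatic: empty admissible grid")
  fit <- new("StaticFit", nStates = 2L, Dslow = best$Ds, Dfast = best$Df,
             fSlow = best$f, fFast = 1 - best$f, sigmaSlow = sigmaSlow,
             sigmaFast = sigmaFast, chi2nu = best$chi,
             constrained = c(Dslow = !is.null(DslowFixed),
                             Dfast = !is.null(DfastFixed),
                             fSlow = !is.null(fSlowFixed)),
             onBoundary = isTRUE(best$onB))
  grid <- new("ChiSqGrid",
              axes = list(Dslow = DsGrid, Dfast = DfGrid, fSlow = fGrid),
              values = vals)
  list(fit = fit, grid = grid)
}

setMethod("show", "StaticFit", function(object) {
  cat(sprintf("StaticFit (%d-state): chi2nu = %.3g%s\n", object@nStates,
              object@chi2nu,
              if (object@onBoundary) " [minimizer on grid boundary]" else ""))
  if (object@nStates == 2L)
    cat(sprintf("  D_slow = %.3g%s, D_fast = %.3g, f_slow = %.3g\n",
                object@Dslow,
                if (object@constrained["Dslow"]) " (fixed)" else "",
                object@Dfast, object@fSlow))
  else cat(sprintf("  D = %.3g\n", object@Dfast))
})

#' @rdname chi2nu
#' @export
setMethod("chi2nu", "StaticFit", function(x) x@chi2nu)
#' @rdname chi2nu
#' @export
setMethod("chi2nu", "KineticFit", function(x) x@chi2nu)

#' Per-parameter confidence ranges from a chi-square grid
#'
#' Returns for each grid axis the min/max parameter value over grid
#' points with chi2nu <= threshold (the error-region convention of
#' simulation-based displacement fitting).
#'
#' @param grid a [ChiSqGrid-class].
#' @param threshold chi2nu cut (default 1.5).
#' @return named list of c(min, max) per parameter.
#' @export
confidenceRegion <- function(grid, threshold = 1.5) {
  ok <- which(grid@values <= threshold, arr.ind = TRUE)
  if (nrow(ok) == 0)
    stop("confidenceRegion: no grid points with chi2nu <= ", threshold,
         " (fit inadequate)")
  if (is.null(dim(ok))) ok <- matrix(ok, ncol = 1)
  res <- list()
  for (j in seq_along(grid@axes)) {
    v <- grid@axes[[j]][ok[, j]]
    res[[names(grid@axes)[j]]] <- c(min = min(v), max = max(v))
  }
  res
}

setMethod("show", "ChiSqGrid", function(object) {
  cat(sprintf("ChiSqGrid over (%s); min chi2nu = %.3g\n",
              paste(names(object@axes), collapse = ", "),
              min(object@values, na.rm = TRUE)))
})

#' Predicted six-step mean distribution for static populations
#'
#' Simulates `round(fSlow * nTraj)` pure-slow and the remaining pure-fast
#' static trajectories (delegating to [simulateEnsemble()] with fixed
#' states) and bins the per-trajectory six-step mean displacements.
#'
#' @param fit a two-state [StaticFit-class].
#' @param config a [SimConfig-class] (nFrames >= 7).
#' @param nTraj total trajectories (e.g. 15,000).
#' @param seed master seed.
#' @param binWidth,rMax binning of the <r>_6 histogram.
#' @return a [DisplacementDistribution-class] of kind "six_step_mean".
#' @export
predictSixStepStatic <- function(fit, config, nTraj, seed,
                                 binWidth = 0.025, rMax = 0.8) {
  stopifnot(is(fit, "StaticFit"), fit@nStates == 2L)
  nSlow <- round(fit@fSlow * nTraj)
  states <- rep(c(1L, 0L), c(nSlow, nTraj - nSlow))
  m <- TwoStateModel(Dslow = fit@Dslow, Dfast = fit@Dfast,
                     fSlow = fit@fSlow,
                     sigmaSlow = fit@sigmaSlow, sigmaFast = fit@sigmaFast)
  ts <- simulateEnsemble(m, config, nTraj, seed, static = TRUE,
                         fixedState = states)
  r6 <- meanSixStep(ts)
  displacementPdf(r6, binWidth = binWidth, rMax = rMax,
                  kind = "six_step_mean")
}

#' Fit exchange lifetimes to a six-step mean displacement distribution
#'
#' Holding D_slow, D_fast, sigma values and the lifetime ratio
#' tau_free/tau_bound = f_fast/f_slow fixed by the static fit, simulates
#' an exchange ensemble for each candidate tau_free, bins the six-step
#' means with the target binning, and minimizes the reduced chi-square
#' (one free parameter). Common random numbers (the same seed stream for
#' every grid point) smooth the objective. An optional refinement pass
#' doubles the grid resolution around the coarse minimum.
#'
#' @param experimentalR6 target distribution (kind "six_step_mean").
#' @param base a two-state [StaticFit-class] supplying D values,
#'   fractions and sigmas.
#' @param tauGrid candidate tau_free values, ms (default 12-point log
#'   grid on [0.1, 100]).
#' @param config a [SimConfig-class] (nFrames >= 7).
#' @param nTraj model trajectories per grid point (default 15,000).
#' @param seed master seed, shared across grid points.
#' @param refine add a x2-resolution pass around the coarse minimum.
#' @return list with `fit` ([KineticFit-class]) and `grid`
#'   ([ChiSqGrid-class] over tau_free, coarse pass only).
#' @export
fitLifetimes <- function(experimentalR6, base, tauGrid = NULL, config,
                         nTraj = 15000L, seed, refine = TRUE) {
  stopifnot(is(base, "StaticFit"), base@nStates == 2L,
            experimentalR6@kind == "six_step_mean")
  if (is.null(tauGrid))
    tauGrid <- 10^seq(log10(0.1), log10(100), length.out = 12)
  ratio <- base@fFast / base@fSlow  # tau_free / tau_bound
  edges <- experimentalR6@binEdges
  evalTau <- function(tf) {
    m <- TwoStateModel(Dslow = base@Dslow, Dfast = base@Dfast,
                       tauFree = tf, tauBound = tf / ratio,
                       sigmaSlow = base@sigmaSlow,
                       sigmaFast = base@sigmaFast)
    ts <- simulateEnsemble(m, config, nTraj, seed)
    r6 <- meanSixStep(ts)
    model <- .binWithEdges(r6, edges, "six_step_mean")
    reducedChiSquare(experimentalR6, model, nFreeParams = 1L)
  }
  chi <- vapply(tauGrid, evalTau, numeric(1))
  i <- which.min(chi)
  bestTau <- tauGrid[i]; bestChi <- chi[i]
  if (refine) {
    lo <- if (i > 1L) tauGrid[i - 1L] else tauGrid[i]
    hi <- if (i < length(tauGrid)) tauGrid[i + 1L] else tauGrid[i]
    extra <- setdiff(10^seq(log10(lo), log10(hi), length.out = 5),
                     tauGrid)
    if (length(extra)) {
      chiR <- vapply(extra, evalTau, numeric(1))
      j <- which.min(chiR)
      if (chiR[j] < bestChi) { bestTau <- extra[j]; bestChi <- chiR[j] }
    }
  }
  fit <- new("KineticFit", tauFree = bestTau, tauBound = bestTau / ratio,
             chi2nu = bestChi, fixedRatio = ratio)
  grid <- new("ChiSqGrid", axes = list(tauFree = tauGrid),
              values = array(chi, dim = length(tauGrid)))
  list(fit = fit, grid = grid)
}

setMethod("show", "KineticFit", function(object) {
  cat(sprintf(
    "KineticFit: tau_free = %.3g ms, tau_bound = %.3g ms (ratio %.3g), chi2nu = %.3g\n",
    object@tauFree, object@tauBound, object@fixedRatio, object@chi2nu))
})
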