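#' Construct a two-state diffusion/kinetics model
#'
#' When `exchange = TRUE`, either supply both lifetimes (the stationary
#' bound fraction is then `tauBound/(tauBound + tauFree)`) or supply
#' `fSlow` together with one lifetime, and the other is derived; supplying
#' all three requires consistency to 1e-9. With `exchange = FALSE` the
#' model describes two static (non-exchanging) populations with fractions
#' `fSlow` and `1 - fSlow`.
#'
#' @param Dslow,Dfast diffusion coefficients in um^2/s (Dfast >= Dslow).
#' @param fSlow stationary bound fraction (derived from the lifetimes if
#'   omitted while exchange is on).
#' @param tauFree,tauBound mean dwell times in ms.
#' @param sigmaSlow,sigmaFast per-coordinate dynamic localization error in
#'   nm for the bound and free states.
#' @param exchange enable binding/unbinding kinetics.
#' @return a [TwoStateModel-class].
#' @examples
#' # wild-type EF-P: 30% bound, tau_free 16 ms, tau_bound 7 ms
#' TwoStateModel(Dslow = 0.2, Dfast = 4.3, tauFree = 16, tauBound = 7,
#'               sigmaSlow = 50, sigmaFast = 75)
#' @export
TwoStateModel <- function(Dslow, Dfast, fSlow = NULL,
                          tauFree = NA_real_, tauBound = NA_real_,
                          sigmaSlow = 0, sigmaFast = 0,
                          exchange = is.finite(tauFree) || is.finite(tauBound)) {
  if (exchange) {
    if (is.null(fSlow)) {
      if (!is.finite(tauFree) || !is.finite(tauBound))
        stop("exchange model needs both lifetimes, or fSlow plus one lifetime")
      fSlow <- tauBound / (tauBound + tauFree)
    } else if (!is.finite(tauBound) && is.finite(tauFree)) {
      tauBound <- tauFree * fSlow / (1 - fSlow)
    } else if (!is.finite(tauFree) && is.finite(tauBound)) {
      tauFree <- tauBound * (1 - fSlow) / fSlow
    }
  } else if (is.null(fSlow)) {
    stop("fSlow is required when exchange is disabled")
  }
  new("TwoStateModel", Dslow = Dslow, Dfast = Dfast, fSlow = fSlow,
      tauFree = tauFree, tauBound = tauBound,
      sigmaSlow = sigmaSlow, sigmaFast = sigmaFast, exchange = exchange)
}

setMethod("show", "TwoStateModel", function(object) {
  cat("TwoStateModel\n")
  cat(sprintf("  D_slow = %g, D_fast = %g um^2/s; f_slow = %.4g\n",
              object@Dslow, object@Dfast, object@fSlow))
  cat(sprintf("  sigma_slow = %g, sigma_fast = %g nm\n",
              object@sigmaSlow, object@sigmaFast))
  if (object@exchange)
    cat(sprintf("  exchange: tau_free = %g ms, tau_bound = %g ms\n",
                object@tauFree, object@tauBound))
  else cat("  static (no exchange)\n")
})

#' Construct a simulation configuration
#'
#' Defaults follow the imaging conditions of fast sptPALM in bacteria:
#' 2 ms frames with continuous 2 ms exposure, 20 Brownian substeps per
#' frame (0.1 ms), confinement on, motion blur on.
#'
#' @param nFrames frames per trajectory.
#' @param cell confining [Spherocylinder-class]; default 4 x 0.9 um.
#' @param frameInterval,exposure ms.
#' @param substepsPerFrame Brownian substeps spanning the exposure.
#' @param blur if TRUE the observed frame position is the mean of the
#'   substep positions within the exposure (motion blur); if FALSE it is
#'   the instantaneous position at the frame start, which makes the
#'   closed-form free-diffusion oracle exact.
#' @param confine confine substeps by rejection resampling.
#' @return a [SimConfig-class].
#' @export
SimConfig <- function(nFrames, cell = Spherocylinder(4, 0.9),
                      frameInterval = 2, exposure = frameInterval,
                      substepsPerFrame = 20L, blur = TRUE, confine = TRUE) {
  new("SimConfig", frameInterval = frameInterval, exposure = exposure,
      substepsPerFrame = as.integer(substepsPerFrame),
      nFrames = as.integer(nFrames), cell = cell, blur = blur,
      confine = confine)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d frames @ %g ms (exposure %g ms, %d substeps), blur=%s, confine=%s\n",
    object@nFrames, object@frameInterval, object@exposure,
    object@substepsPerFrame, object@blur, object@confine))
  show(object@cell)
})
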