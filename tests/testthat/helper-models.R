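# Shared model/config fixtures and a memoized fitting library.

efpModel <- function() {
  TwoStateModel(Dslow = 0.2, Dfast = 4.3, tauFree = 16, tauBound = 7,
                sigmaSlow = 50, sigmaFast = 75)
}

efpStaticModel <- function() {
  TwoStateModel(Dslow = 0.2, Dfast = 4.3, fSlow = 0.30,
                sigmaSlow = 50, sigmaFast = 75)
}

stdConfig <- function(nFrames = 7L, ...) SimConfig(nFrames = nFrames, ...)

# unconfined, blur-off configuration for closed-form oracles
freeConfig <- function(nFrames = 7L) {
  SimConfig(nFrames = nFrames, cell = Spherocylinder(400, 90),
            blur = FALSE, confine = FALSE)
}

prEdges <- function() seq(0, 1.2, by = 0.025)

# EF-P fitting library (D grid x sigma {50, 75}); built once per session
efpLibrary <- local({
  lib <- NULL
  function() {
    if (is.null(lib))
      lib <<- buildModelLibrary(defaultDGrid(), c(50, 75), stdConfig(),
                                nTraj = 10000, seed = 99,
                                binEdges = prEdges())
    lib
  }
})

# kernel density modes: peaks with height >= 10% of the maximum, and the
# trough-to-lower-peak ratio between the two tallest modes
densityModes <- function(v, bw = 0.008, to = 0.6) {
  d <- stats::density(v, bw = bw, from = 0, to = to)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] >= 0.1 * max(y)]
  if (length(pk) < 2)
    return(list(nModes = length(pk), troughRatio = NA_real_))
  top <- pk[order(-y[pk])][1:2]
  lo <- min(top); hi <- max(top)
  tr <- lo + which.min(y[lo:hi]) - 1
  list(nModes = length(pk), troughRatio = y[tr] / min(y[top]))
}
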