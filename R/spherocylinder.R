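#' Construct a spherocylindrical cell
#'
#' @param totalLength tip-to-tip length L in micrometres.
#' @param diameter cell diameter d in micrometres.
#' @return a [Spherocylinder-class] object.
#' @examples
#' cell <- Spherocylinder(4, 0.9)
#' cylinderHalfLength(cell)  # 1.55 um
#' @export
Spherocylinder <- function(totalLength, diameter) {
  new("Spherocylinder", totalLength = as.numeric(totalLength),
      diameter = as.numeric(diameter))
}

#' @rdname Spherocylinder
#' @param x a `Spherocylinder`.
#' @export
setMethod("totalLength", "Spherocylinder", function(x) x@totalLength)
#' @rdname Spherocylinder
#' @export
setMethod("cellDiameter", "Spherocylinder", function(x) x@diameter)
#' @rdname Spherocylinder
#' @export
setMethod("cylinderHalfLength", "Spherocylinder",
          function(x) (x@totalLength - x@diameter) / 2)
#' @rdname Spherocylinder
#' @export
setMethod("capRadius", "Spherocylinder", function(x) x@diameter / 2)

setMethod("show", "Spherocylinder", function(object) {
  cat(sprintf("Spherocylinder: L = %g um, d = %g um (a = %g, r_c = %g)\n",
              object@totalLength, object@diameter,
              cylinderHalfLength(object), capRadius(object)))
})

#' Test whether points lie inside a spherocylinder
#'
#' Boundary-inclusive containment: a point is inside iff it lies in the
#' central cylinder (|x| <= a, y^2 + z^2 <= r_c^2) or in one of the
#' hemispherical caps ((|x| - a)^2 + y^2 + z^2 <= r_c^2 for |x| > a).
#'
#' @param cell a [Spherocylinder-class].
#' @param x,y,z coordinates in micrometres (vectorized); x is axial with
#'   origin at the cell centre.
#' @return logical vector.
#' @export
containsPoint <- function(cell, x, y, z) {
  stopifnot(is(cell, "Spherocylinder"))
  a <- cylinderHalfLength(cell)
  rc2 <- capRadius(cell)^2
  ax <- abs(x)
  yz2 <- y^2 + z^2
  ifelse(ax <= a, yz2 <= rc2, (ax - a)^2 + yz2 <= rc2)
}

#' Confine a diffusive step by Metropolis rejection
#'
#' Proposes `current + delta` with `delta` drawn from `stepSampler`; a
#' proposal that leaves the cell is rejected and the walker stays at
#' `current` for this step. With a symmetric step distribution this
#' rejection rule preserves the uniform equilibrium distribution exactly
#' and is unambiguous at the cap/cylinder junction. (Redrawing the
#' displacement until the result lands inside does not preserve
#' uniformity: the stationary density of that chain is proportional to
#' the in-domain proposal mass, which is depleted within roughly one
#' step length of the wall.)
#'
#' @param cell a [Spherocylinder-class].
#' @param current numeric length-3 position inside the cell.
#' @param stepSampler function() returning a numeric length-3 displacement.
#' @return the confined new position (numeric length 3); always inside
#'   the cell.
#' @export
confineStep <- function(cell, current, stepSampler) {
  stopifnot(containsPoint(cell, current[1], current[2], current[3]))
  p <- current + stepSampler()
  if (containsPoint(cell, p[1], p[2], p[3])) p else current
}

#' Sample points uniformly over a spherocylinder volume
#'
#' @param cell a [Spherocylinder-class].
#' @param n number of points.
#' @param seed integer seed (RNG state is restored on exit).
#' @return data.frame with columns x, y, z (micrometres).
#' @export
sampleUniform <- function(cell, n, seed) {
  stopifnot(n >= 1)
  withSeed(seed, {
    L <- totalLength(cell); d <- cellDiameter(cell)
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      m <- max(2L * (n - nrow(out)), 16L)
      x <- runif(m, -L / 2, L / 2)
      y <- runif(m, -d / 2, d / 2)
      z <- runif(m, -d / 2, d / 2)
      keep <- containsPoint(cell, x, y, z)
      out <- rbind(out, cbind(x, y, z)[keep, , drop = FALSE])
    }
    out <- out[seq_len(n), , drop = FALSE]
    data.frame(x = out[, 1], y = out[, 2], z = out[, 3])
  })
}

#' Closed-form axial profile of a uniformly filled spherocylinder
#'
#' Projects the uniform volume density onto the long axis: cross-section
#' area is pi r_c^2 along the cylindrical body and
#' pi (r_c^2 - (|x| - a)^2) across the caps. The area is integrated over
#' each bin and normalized, with the axis reported on the scaled
#' [-0.5, +0.5] coordinate. This is the "no binding" null against which
#' measured axial distributions are compared.
#'
#' @param cell a [Spherocylinder-class].
#' @param nBins number of bins (>= 2) spanning [-0.5, 0.5].
#' @return an [AxialProfile-class].
#' @export
uniformAxialProfile <- function(cell, nBins) {
  stopifnot(nBins >= 2)
  L <- totalLength(cell)
  a <- cylinderHalfLength(cell)
  rc <- capRadius(cell)
  edges <- seq(-0.5, 0.5, length.out = nBins + 1L)
  # antiderivative of the cross-section area in physical axial units
  areaInt <- function(x) {
    x <- pmin(pmax(x, -L / 2), L / 2)
    s <- sign(x); ax <- abs(x)
    cyl <- pi * rc^2 * pmin(ax, a)
    u <- pmax(ax - a, 0)
    cap <- pi * (rc^2 * u - u^3 / 3)
    s * (cyl + cap)
  }
  phys <- edges * L
  mass <- diff(areaInt(phys))
  new("AxialProfile", binEdges = edges, probability = mass / sum(mass))
}

#' Scale axial positions to the relative [-0.5, 0.5] coordinate
#'
#' Cell-frame axial positions (origin at cell centre) are divided by the
#' cell length; out-of-range positions are an error, not clipped.
#'
#' @param x axial positions in micrometres, cell frame.
#' @param cellLength tip-to-tip cell length in micrometres.
#' @return scaled coordinates in [-0.5, 0.5].
#' @export
scaleAxial <- function(x, cellLength) {
  if (any(abs(x) > cellLength / 2 + 1e-12))
    stop("scaleAxial: positions outside +/- cellLength/2")
  x / cellLength
}

setMethod("show", "AxialProfile", function(object) {
  cat(sprintf("AxialProfile: %d bins on [-0.5, 0.5]\n",
              length(object@probability)))
})

#' @rdname uniformAxialProfile
#' @export
setMethod("binEdges", "AxialProfile", function(x) x@binEdges)
#' @rdname uniformAxialProfile
#' @export
setMethod("probability", "AxialProfile", function(x) x@probability)
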