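#' @rdname Spherocylinder
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))
#' @rdname Spherocylinder
#' @export
setGeneric("cellDiameter", function(x) standardGeneric("cellDiameter"))
#' @rdname Spherocylinder
#' @export
setGeneric("cylinderHalfLength", function(x) standardGeneric("cylinderHalfLength"))
#' @rdname Spherocylinder
#' @export
setGeneric("capRadius", function(x) standardGeneric("capRadius"))

#' @rdname TrajectorySet
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname TrajectorySet
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname TrajectorySet
#' @export
setGeneric("nTrajectories", function(x) standardGeneric("nTrajectories"))

#' @rdname displacementPdf
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname displacementPdf
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname displacementPdf
#' @export
setGeneric("probability", function(x) standardGeneric("probability"))
#' @rdname displacementPdf
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' Reduced chi-square of a fit object
#' @param x a `StaticFit` or `KineticFit`.
#' @return the reduced chi-square at the best-fit point.
#' @export
setGeneric("chi2nu", function(x) standardGeneric("chi2nu"))
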