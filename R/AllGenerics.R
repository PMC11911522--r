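#' @rdname proportions
#' @export
setGeneric("proportions", function(x, ...) standardGeneric("proportions"))

#' @rdname profiles
#' @export
setGeneric("profiles", function(x, ...) standardGeneric("profiles"))

#' @rdname markers
#' @export
setGeneric("markers", function(x, ...) standardGeneric("markers"))

#' @rdname selectedGenes
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname bestK
#' @export
setGeneric("bestK", function(x) standardGeneric("bestK"))

#' @rdname spotCoords
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' @rdname isLogNormalized
#' @export
setGeneric("isLogNormalized", function(x) standardGeneric("isLogNormalized"))

#' @rdname trueProportions
#' @export
setGeneric("trueProportions", function(x) standardGeneric("trueProportions"))

#' Project points into / lift points out of an affine subspace
#'
#' @param x an [AffineProjection-class].
#' @param points for `projectPoints`, an N x S matrix of ambient points;
#'   for `liftPoints`, an N x (K-1) matrix of projected coordinates.
#' @return `projectPoints`: N x (K-1) coordinates; `liftPoints`: N x S
#'   ambient points.
#' @name affine-maps
NULL

#' @rdname affine-maps
#' @export
setGeneric("projectPoints", function(x, points) standardGeneric("projectPoints"))

#' @rdname affine-maps
#' @export
setGeneric("liftPoints", function(x, points) standardGeneric("liftPoints"))
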