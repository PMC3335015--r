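#' Accessors for cortdev classes
#'
#' Small accessor generics in the Bioconductor style; use these rather than
#' reaching into slots.
#'
#' @param x,object an object of the documented class.
#' @return The accessed component.
#' @name cortdev-accessors
NULL

#' @rdname cortdev-accessors
#' @export
setGeneric("meshCoordinates", function(x) standardGeneric("meshCoordinates"))

#' @rdname cortdev-accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname cortdev-accessors
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))

#' @rdname cortdev-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname cortdev-accessors
#' @export
setGeneric("surfaceMesh", function(x) standardGeneric("surfaceMesh"))

#' @rdname cortdev-accessors
#' @export
setGeneric("thickness", function(x) standardGeneric("thickness"))

#' @rdname cortdev-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' Effective degrees of freedom
#'
#' The trace of a linear smoother operator, or the achieved effective df of
#' a fitted smoother. The constant fit has df 1, the global least-squares
#' line df 2, and running-line smooths interpolate above 2.
#'
#' @param x a square smoother operator matrix, or a [SmootherFit-class].
#' @return A single numeric df value.
#' @examples
#' ages <- seq(6, 14, length.out = 20)
#' effectiveDf(smootherMatrix(ages, span = 1, kernel = "uniform"))  # 2
#' @export
setGeneric("effectiveDf", function(x) standardGeneric("effectiveDf"))

#' @rdname cortdev-accessors
#' @export
setGeneric("rss", function(x) standardGeneric("rss"))

#' @rdname cortdev-accessors
#' @export
setGeneric("chosenDf", function(x) standardGeneric("chosenDf"))

#' @rdname cortdev-accessors
#' @export
setGeneric("chosenFit", function(x) standardGeneric("chosenFit"))

#' @rdname cortdev-accessors
#' @export
setGeneric("stepTests", function(x) standardGeneric("stepTests"))

#' @rdname cortdev-accessors
#' @export
setGeneric("vertexStats", function(x) standardGeneric("vertexStats"))

#' @rdname cortdev-accessors
#' @export
setGeneric("criticalStatistic", function(x) standardGeneric("criticalStatistic"))
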