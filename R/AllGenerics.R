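#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the classes in \pkg{cytomech}. Each has a
#' method for the class that carries the corresponding slot; none of them
#' exposes raw slot access to user code.
#'
#' @param object an object of one of the \pkg{cytomech} classes.
#' @return The slot value (see the class documentation for units).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("maskArea", function(object) standardGeneric("maskArea"))

#' @rdname accessors
#' @export
setGeneric("skeletonMask", function(object) standardGeneric("skeletonMask"))

#' @rdname accessors
#' @export
setGeneric("skeletonLength", function(object) standardGeneric("skeletonLength"))

#' @rdname accessors
#' @export
setGeneric("branchpointCount", function(object) standardGeneric("branchpointCount"))

#' @rdname accessors
#' @export
setGeneric("mtDensity", function(object) standardGeneric("mtDensity"))

#' @rdname accessors
#' @export
setGeneric("crossingDensity", function(object) standardGeneric("crossingDensity"))

#' @rdname accessors
#' @export
setGeneric("bestAngle", function(object) standardGeneric("bestAngle"))

#' @rdname accessors
#' @export
setGeneric("filterResponse", function(object) standardGeneric("filterResponse"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("alignmentValues", function(object) standardGeneric("alignmentValues"))

#' @rdname accessors
#' @export
setGeneric("youngsModulus", function(object) standardGeneric("youngsModulus"))

#' @rdname accessors
#' @export
setGeneric("contactPoint", function(object) standardGeneric("contactPoint"))
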