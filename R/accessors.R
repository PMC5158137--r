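#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("pixels", "FilamentImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSize", "FilamentImage", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setMethod("imageId", "FilamentImage", function(object) object@id)

#' @rdname accessors
#' @export
setMethod("maskArea", "CellMask", function(object) object@area)

#' Binary mask of a CellMask
#' @param object a \code{CellMask}.
#' @return logical matrix.
#' @export
cellMask <- function(object) object@mask

#' @rdname accessors
#' @export
setMethod("skeletonMask", "MorphometryResult", function(object) object@skeleton)

#' @rdname accessors
#' @export
setMethod("skeletonLength", "MorphometryResult",
          function(object) object@skeletonLength)

#' @rdname accessors
#' @export
setMethod("branchpointCount", "MorphometryResult",
          function(object) object@branchpointCount)

#' @rdname accessors
#' @export
setMethod("mtDensity", "MorphometryResult", function(object) object@mtDensity)

#' @rdname accessors
#' @export
setMethod("crossingDensity", "MorphometryResult",
          function(object) object@crossingDensity)

#' @rdname accessors
#' @export
setMethod("bestAngle", "OrientationField", function(object) object@angle)

#' @rdname accessors
#' @export
setMethod("filterResponse", "OrientationField",
          function(object) object@response)

#' @rdname accessors
#' @export
setMethod("validMask", "OrientationField", function(object) object@valid)

#' @rdname accessors
#' @export
setMethod("alignmentValues", "AlignmentMap", function(object) object@S)

#' @rdname accessors
#' @export
setMethod("youngsModulus", "HertzFitResult", function(object) object@E)

#' @rdname accessors
#' @export
setMethod("contactPoint", "HertzFitResult", function(object) object@z0)

#' @rdname accessors
#' @export
setMethod("contactPoint", "IndentationCurve", function(object) object@z0)

## show methods -------------------------------------------------------------

setMethod("show", "FilamentImage", function(object) {
  cat("FilamentImage '", object@id, "': ", nrow(object@pixels), " x ",
      ncol(object@pixels), " px, ", object@pixelSize, " nm/px\n", sep = "")
})

setMethod("show", "MorphometryResult", function(object) {
  cat("MorphometryResult: skeleton length ", object@skeletonLength,
      " px, ", object@branchpointCount, " branch point(s)\n",
      "  MT density ", signif(object@mtDensity, 4), " px^-1, crossing density ",
      if (object@crossingDefined) signif(object@crossingDensity, 4)
      else "undefined", " px^-1\n", sep = "")
})

setMethod("show", "OrientationField", function(object) {
  cat("OrientationField: ", nrow(object@angle), " x ", ncol(object@angle),
      " px, ", length(object@angleSet), " probed angles, ",
      sum(object@valid), " MT pixel(s)\n", sep = "")
})

setMethod("show", "AlignmentMap", function(object) {
  v <- object@S[!is.na(object@S)]
  cat("AlignmentMap (window ", object@windowDiameter, " px): ",
      length(v), " valid pixel(s)",
      if (length(v)) paste0(", mean S ", signif(mean(v), 4)), "\n", sep = "")
})

setMethod("show", "ForceCurve", function(object) {
  cat("ForceCurve '", object@id, "': ", length(object@z),
      " samples, z in [", min(object@z), ", ", max(object@z),
      "] nm, k = ", object@k, " N/m, Rs = ", object@Rs, " nm\n", sep = "")
})

setMethod("show", "HertzFitResult", function(object) {
  cat("HertzFitResult [", object@status, "]: E = ", signif(object@E, 5),
      " Pa, z0 = ", signif(object@z0, 6), " nm at depth ", object@fitDepth,
      " nm (", object@nPoints, " points, RMS ",
      signif(object@rmsResidual, 3), " nN)\n", sep = "")
})

setMethod("show", "Report", function(object) {
  cat("cytomech Report: ", nrow(object@morphometry), " morphometry row(s), ",
      nrow(object@elasticity), " elasticity row(s), seed ",
      object@provenance$seed, "\n", sep = "")
})
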