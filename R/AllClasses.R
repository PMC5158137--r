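#' cytomech: microtubule network morphometry and AFM cell elasticity
#'
#' Tools to quantify the morphology of microtubule networks in
#' reconstructed superresolution images (density, crossing density, local
#' axial alignment by angle doubling) and to estimate cell stiffness from
#' AFM force-distance curves by fitting the Sneddon spherical-indenter
#' contact model. A synthetic-data module provides ground-truthed inputs
#' for both analysis arms.
#'
#' @import methods
#' @importFrom stats rnorm runif lm coef median optimize pnorm sd t.test quantile
#' @importFrom utils combn write.csv read.csv
#' @name cytomech-package
#' @aliases cytomech
"_PACKAGE"

## ---------------------------------------------------------------------------
## Imaging side
## ---------------------------------------------------------------------------

#' FilamentImage: a 2-D grayscale image with physical pixel size
#'
#' Container for a single reconstructed superresolution field (one cell per
#' field). Intensities are arbitrary non-negative units; the pixel size is
#' carried in nm so that densities can be reported in physical units when
#' desired (all core metrics are per-pixel, as in the source analyses).
#'
#' @slot pixels numeric matrix of finite, non-negative intensities
#'   (rows = image rows).
#' @slot pixelSize physical size of one pixel, nm.
#' @slot id identifier string.
#' @export
setClass("FilamentImage",
  representation(pixels = "matrix", pixelSize = "numeric", id = "character"),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (any(!is.finite(object@pixels))) return("pixels must be finite")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) return("pixelSize must be a single positive number")
    TRUE
  })

#' Construct a FilamentImage
#'
#' @param pixels numeric intensity matrix.
#' @param pixelSize nm per pixel (default 20, typical of dSTORM
#'   reconstructions).
#' @param id identifier string.
#' @return A [FilamentImage-class] object.
#' @examples
#' img <- FilamentImage(matrix(0, 64, 64))
#' dim(pixels(img))
#' @export
FilamentImage <- function(pixels, pixelSize = 20, id = "image") {
  new("FilamentImage", pixels = as.matrix(pixels), pixelSize = pixelSize,
      id = as.character(id))
}

#' CellMask: binary mask of the imaged cell area
#'
#' @slot mask logical matrix; TRUE inside the cell.
#' @slot area number of TRUE pixels (pixel^2).
#' @export
setClass("CellMask",
  representation(mask = "matrix", area = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (object@area != sum(object@mask)) return("area must equal number of TRUE pixels")
    TRUE
  })

#' @rdname CellMask-class
#' @param mask logical matrix.
#' @return A validated \code{CellMask}.
#' @export
CellMask <- function(mask) new("CellMask", mask = mask, area = sum(mask))

#' MorphometryResult: skeleton-based network metrics for one cell
#'
#' Skeleton length is the skeleton pixel count (optionally geodesically
#' weighted); microtubule density is skeleton length divided by cell area,
#' and crossing density is the number of merged branch points divided by
#' skeleton length. Crossing density is undefined (NA, flagged) for an
#' empty skeleton.
#'
#' @slot skeleton logical matrix, the 1-px-wide skeleton.
#' @slot branchMask logical matrix of branch-point pixels.
#' @slot skeletonLength numeric, pixels.
#' @slot branchpointCount integer count of merged branch points.
#' @slot mtDensity numeric, pixel^-1.
#' @slot crossingDensity numeric, pixel^-1 (NA when undefined).
#' @slot crossingDefined logical flag.
#' @export
setClass("MorphometryResult",
  representation(skeleton = "matrix", branchMask = "matrix",
                 skeletonLength = "numeric", branchpointCount = "integer",
                 mtDensity = "numeric", crossingDensity = "numeric",
                 crossingDefined = "logical"),
  validity = function(object) {
    if (object@skeletonLength < 0) return("skeletonLength must be >= 0")
    if (object@branchpointCount < 0) return("branchpointCount must be >= 0")
    if (object@mtDensity < 0) return("mtDensity must be >= 0")
    if (object@crossingDefined && (is.na(object@crossingDensity) ||
        object@crossingDensity < 0))
      return("crossingDensity must be >= 0 when defined")
    TRUE
  })

#' OrientationField: per-pixel axial orientation from the rotating filter
#'
#' Angles are axial (degrees in [0, 180)) and restricted to the configured
#' angle set; the response is the maximal rotating-filter response at each
#' pixel and the validity mask marks microtubule pixels.
#'
#' @slot angle numeric matrix of best angles, degrees.
#' @slot response numeric matrix of maximal filter responses (>= 0).
#' @slot valid logical matrix (MT pixels).
#' @slot angleSet numeric vector of probed angles, degrees.
#' @export
setClass("OrientationField",
  representation(angle = "matrix", response = "matrix", valid = "matrix",
                 angleSet = "numeric"),
  validity = function(object) {
    ok <- object@angle[object@valid]
    if (length(ok) && !all(ok %in% object@angleSet))
      return("angles must belong to angleSet")
    if (any(object@response < 0)) return("response must be >= 0")
    TRUE
  })

#' AlignmentMap: local angle-doubled mean resultant length
#'
#' Per-pixel statistic S in [0, 1]: the length of the mean unit vector of
#' doubled axial angles over microtubule pixels inside a circular window.
#' S = 1 means locally parallel filaments, values toward 0 mean locally
#' disordered orientations. (This is the quantity the source analyses call
#' "angular variance" with value one when parallel; conventionally it is
#' the mean resultant length, and circular variance would be 1 - S.)
#'
#' @slot S numeric matrix in [0, 1]; NA where no MT pixel falls in the
#'   window.
#' @slot windowDiameter window diameter, pixels.
#' @export
setClass("AlignmentMap",
  representation(S = "matrix", windowDiameter = "numeric"),
  validity = function(object) {
    v <- object@S[!is.na(object@S)]
    if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
      return("S must lie in [0, 1]")
    TRUE
  })

## ---------------------------------------------------------------------------
## Synthetic network generator
## ---------------------------------------------------------------------------

#' NetworkSpec: parameters of a synthetic filament-network image
#'
#' Filaments are straight lines clipped to the frame; orientations are
#' axial (mod 180 degrees). Rendering dilates the centerlines to the
#' requested width, blurs and adds Gaussian noise on a constant
#' background.
#'
#' @slot imageSize integer c(H, W), each >= 64.
#' @slot nFilaments integer >= 0.
#' @slot orientationMode one of "single_angle", "uniform_axial",
#'   "wrapped_dispersion".
#' @slot meanAngle degrees in [0, 180).
#' @slot dispersion non-negative concentration of the wrapped orientation
#'   distribution on doubled angles (0 = uniform over [0, 180)).
#' @slot filamentWidth rendered width, pixels (>= 1).
#' @slot blurSigma Gaussian blur sigma, pixels (0 = none).
#' @slot backgroundLevel,noiseSd background intensity and additive
#'   Gaussian noise SD, intensity units.
#' @slot seed integer RNG seed; identical spec => bit-identical output.
#' @export
setClass("NetworkSpec",
  representation(imageSize = "integer", nFilaments = "integer",
                 orientationMode = "character", meanAngle = "numeric",
                 dispersion = "numeric", filamentWidth = "numeric",
                 blurSigma = "numeric", backgroundLevel = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@imageSize) != 2L || any(object@imageSize < 64L))
      return("imageSize must be two integers >= 64")
    if (object@nFilaments < 0L) return("nFilaments must be >= 0")
    if (!object@orientationMode %in%
        c("single_angle", "uniform_axial", "wrapped_dispersion"))
      return("orientationMode must be one of single_angle, uniform_axial, wrapped_dispersion")
    if (object@meanAngle < 0 || object@meanAngle >= 180)
      return("meanAngle must lie in [0, 180)")
    if (object@dispersion < 0) return("dispersion must be >= 0")
    if (object@filamentWidth < 1) return("filamentWidth must be >= 1")
    if (object@blurSigma < 0) return("blurSigma must be >= 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })

#' @rdname NetworkSpec-class
#' @param imageSize,nFilaments,orientationMode,meanAngle,dispersion
#'   see slots.
#' @param filamentWidth,blurSigma,backgroundLevel,noiseSd,seed see slots.
#' @return A validated \code{NetworkSpec}.
#' @export
NetworkSpec <- function(imageSize = c(256L, 256L), nFilaments = 40L,
                        orientationMode = "wrapped_dispersion",
                        meanAngle = 0, dispersion = 2, filamentWidth = 3,
                        blurSigma = 1, backgroundLevel = 0.05,
                        noiseSd = 0.02, seed = 1L) {
  new("NetworkSpec", imageSize = as.integer(imageSize),
      nFilaments = as.integer(nFilaments),
      orientationMode = orientationMode, meanAngle = meanAngle,
      dispersion = dispersion, filamentWidth = filamentWidth,
      blurSigma = blurSigma, backgroundLevel = backgroundLevel,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' NetworkGroundTruth: exact description of a generated network
#'
#' Computed before rendering and therefore independent of blur, noise and
#' any downstream detector.
#'
#' @slot angles per-filament axial angle, degrees in [0, 180).
#' @slot centerlines list of integer matrices (row, col) of centerline
#'   pixels per filament.
#' @slot centerlineLength total centerline length, pixels (sum of
#'   per-filament pixel counts).
#' @slot crossingCount number of pairwise centerline intersections inside
#'   the frame.
#' @slot resultantLength axial mean resultant length of the filament
#'   angle population, in [0, 1].
#' @export
setClass("NetworkGroundTruth",
  representation(angles = "numeric", centerlines = "list",
                 centerlineLength = "numeric", crossingCount = "integer",
                 resultantLength = "numeric"),
  validity = function(object) {
    n <- length(object@angles)
    if (object@crossingCount > n * (n - 1) / 2)
      return("crossingCount exceeds the pairwise maximum")
    if (n > 0 && (object@resultantLength < 0 ||
                  object@resultantLength > 1 + 1e-12))
      return("resultantLength must lie in [0, 1]")
    TRUE
  })

## ---------------------------------------------------------------------------
## AFM side
## ---------------------------------------------------------------------------

#' CurveSpec: parameters of a synthetic AFM approach curve
#'
#' Forward model: below the contact point the deflection is a linear
#' baseline; beyond it the deflection d solves the self-consistency
#' d = F(delta)/k with delta = (z - z0) - d and F the Sneddon sphere
#' force. Gaussian noise is added to the deflection.
#'
#' @slot youngsModulus E, Pa (> 0).
#' @slot poissonRatio nu in [0, 0.5] (0.5 for cells).
#' @slot beadRadius Rs, nm (2250 nm for the 4.5 um silica bead).
#' @slot springConstant k, N/m (e.g. 0.08 or 0.32).
#' @slot contactPoint z0, nm.
#' @slot zRange c(min, max) piezo range, nm.
#' @slot zStep sampling step, nm.
#' @slot deflectionNoiseSd nm.
#' @slot baselineSlope pre-contact drift, nm per nm.
#' @slot seed integer RNG seed.
#' @export
setClass("CurveSpec",
  representation(youngsModulus = "numeric", poissonRatio = "numeric",
                 beadRadius = "numeric", springConstant = "numeric",
                 contactPoint = "numeric", zRange = "numeric",
                 zStep = "numeric", deflectionNoiseSd = "numeric",
                 baselineSlope = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@youngsModulus <= 0) return("youngsModulus must be > 0")
    if (object@poissonRatio < 0 || object@poissonRatio > 0.5)
      return("poissonRatio must lie in [0, 0.5]")
    if (object@beadRadius <= 0) return("beadRadius must be > 0")
    if (object@springConstant <= 0) return("springConstant must be > 0")
    if (length(object@zRange) != 2L || diff(object@zRange) <= 0)
      return("zRange must be an increasing pair")
    if (object@zStep <= 0) return("zStep must be > 0")
    if (object@deflectionNoiseSd < 0) return("deflectionNoiseSd must be >= 0")
    TRUE
  })

#' @rdname CurveSpec-class
#' @param youngsModulus,poissonRatio,beadRadius,springConstant see slots.
#' @param contactPoint,zRange,zStep,deflectionNoiseSd,baselineSlope,seed
#'   see slots.
#' @return A validated \code{CurveSpec}.
#' @export
CurveSpec <- function(youngsModulus = 500, poissonRatio = 0.5,
                      beadRadius = 2250, springConstant = 0.08,
                      contactPoint = 600, zRange = c(0, 1800), zStep = 5,
                      deflectionNoiseSd = 1, baselineSlope = 0, seed = 1L) {
  new("CurveSpec", youngsModulus = youngsModulus,
      poissonRatio = poissonRatio, beadRadius = beadRadius,
      springConstant = springConstant, contactPoint = contactPoint,
      zRange = zRange, zStep = zStep,
      deflectionNoiseSd = deflectionNoiseSd,
      baselineSlope = baselineSlope, seed = as.integer(seed))
}

#' ForceCurve: an AFM approach curve with calibration constants
#'
#' @slot z piezo displacement samples, nm, strictly increasing.
#' @slot d cantilever deflection samples, nm.
#' @slot k spring constant, N/m.
#' @slot Rs bead radius, nm.
#' @slot nu sample Poisson ratio.
#' @slot id identifier string.
#' @export
setClass("ForceCurve",
  representation(z = "numeric", d = "numeric", k = "numeric",
                 Rs = "numeric", nu = "numeric", id = "character"),
  validity = function(object) {
    if (length(object@z) != length(object@d))
      return("z and d must have equal length")
    if (length(object@z) > 1 && any(diff(object@z) <= 0))
      return("z must be strictly increasing")
    if (object@k <= 0) return("k must be > 0")
    if (object@Rs <= 0) return("Rs must be > 0")
    if (object@nu < 0 || object@nu > 0.5) return("nu must lie in [0, 0.5]")
    TRUE
  })

#' Construct a ForceCurve
#'
#' @param z piezo positions; units set by \code{zUnit}.
#' @param d deflections, same unit as z.
#' @param k spring constant, N/m.
#' @param Rs bead radius, nm.
#' @param nu Poisson ratio (default 0.5).
#' @param id identifier.
#' @param zUnit "nm" or "um"; inputs are converted to nm internally.
#' @return A [ForceCurve-class] object (z and d in nm).
#' @export
ForceCurve <- function(z, d, k, Rs, nu = 0.5, id = "curve", zUnit = "nm") {
  f <- switch(match.arg(zUnit, c("nm", "um")), nm = 1, um = 1000)
  new("ForceCurve", z = as.numeric(z) * f, d = as.numeric(d) * f,
      k = k, Rs = Rs, nu = nu, id = as.character(id))
}

#' IndentationCurve: force-indentation representation of an approach curve
#'
#' @slot delta indentation samples, nm (negative before contact).
#' @slot force force samples, nN (k times baseline-corrected deflection).
#' @slot z0 contact point used for the conversion, nm.
#' @slot preContact logical flags, TRUE where delta < 0.
#' @export
setClass("IndentationCurve",
  representation(delta = "numeric", force = "numeric", z0 = "numeric",
                 preContact = "logical"),
  validity = function(object) {
    if (length(object@delta) != length(object@force))
      return("delta and force must have equal length")
    TRUE
  })

#' HertzFitResult: fitted Young's modulus for one curve at one depth
#'
#' @slot E Young's modulus, Pa.
#' @slot z0 fitted contact point, nm.
#' @slot fitDepth indentation window upper edge, nm.
#' @slot rmsResidual residual RMS over the fitted samples, nN.
#' @slot nPoints number of in-window samples.
#' @slot status "ok" or a diagnostic string.
#' @export
setClass("HertzFitResult",
  representation(E = "numeric", z0 = "numeric", fitDepth = "numeric",
                 rmsResidual = "numeric", nPoints = "integer",
                 status = "character"),
  validity = function(object) {
    if (object@status == "ok" && object@E <= 0) return("E must be > 0")
    TRUE
  })

## ---------------------------------------------------------------------------
## Pipeline report
## ---------------------------------------------------------------------------

#' Report: end-to-end pipeline output
#'
#' @slot morphometry per-cell morphometry table (one row per image).
#' @slot elasticity per-curve-by-depth elasticity table.
#' @slot summaries named list of group-summary tables.
#' @slot provenance named list: config echo (with defaults), package
#'   version, seed, config hash.
#' @export
setClass("Report",
  representation(morphometry = "data.frame", elasticity = "data.frame",
                 summaries = "list", provenance = "list"))
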