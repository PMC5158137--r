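## Axial orientation analysis: rotating linear structuring element and
## the local angle-doubled mean resultant length.

#' Per-pixel axial orientation by a rotating linear structuring element
#'
#' For each probed angle the mask (default) or grayscale image is opened
#' with a digitized (Bresenham) line of \code{elementLength} pixels at
#' that angle; the per-pixel response is the opened value and the best
#' angle is the argmax over the angle set, ties broken to the smallest
#' angle. Orientation is axial: angles live in [0, 180), probed at
#' \code{angleStep} increments from 0 (no polarity information in the
#' signal).
#'
#' @param mask logical MT mask (binarised image); also used as the
#'   validity mask of the result.
#' @param image optional numeric matrix; when supplied with
#'   \code{substrate = "grayscale"} the grayscale opening of the image is
#'   used as response instead of the binary opening of the mask.
#' @param elementLength line length, pixels; odd, >= 3 (default 11).
#' @param angleStep probing step, degrees (default 10; angle set
#'   0, 10, ..., 170).
#' @param substrate "binary" (default) or "grayscale".
#' @return An [OrientationField-class].
#' @export
orientationMap <- function(mask, image = NULL, elementLength = 11,
                           angleStep = 10,
                           substrate = c("binary", "grayscale")) {
  substrate <- match.arg(substrate)
  stopifnot(is.logical(mask), elementLength >= 3,
            elementLength %% 2 == 1)
  if (nrow(mask) < elementLength || ncol(mask) < elementLength)
    stop("image smaller than the structuring element")
  angles <- seq(0, 180 - angleStep, by = angleStep)
  best <- matrix(angles[1], nrow(mask), ncol(mask))
  resp <- matrix(-Inf, nrow(mask), ncol(mask))
  for (th in angles) {
    off <- lineOffsets(elementLength, th)
    r <- if (substrate == "binary") {
      binOpen(mask, off) * 1
    } else {
      kern <- matrix(0L, 2 * max(abs(off[, 1])) + 1,
                     2 * max(abs(off[, 2])) + 1)
      kern[cbind(off[, 1] + max(abs(off[, 1])) + 1,
                 off[, 2] + max(abs(off[, 2])) + 1)] <- 1L
      m <- EBImage::imageData(EBImage::opening(
        EBImage::Image(asMatrixImage(image)), kern))
      matrix(m, nrow(mask), ncol(mask))
    }
    upd <- r > resp                     # strict: smallest angle wins ties
    best[upd] <- th
    resp[upd] <- r[upd]
  }
  resp[!is.finite(resp)] <- 0
  new("OrientationField", angle = best, response = resp, valid = mask,
      angleSet = angles)
}

#' Local angle-doubled alignment statistic
#'
#' For every pixel, over the MT pixels inside a circular window of the
#' configured diameter (truncated at the frame border, no padding),
#' computes \eqn{S = |\,\mathrm{mean}_j\, e^{2 i \theta_j}\,|}, the mean
#' resultant length of the doubled axial angles. S = 1 for locally
#' parallel filaments and decreases toward 0 with increasing local
#' orientation disorder; pixels with no MT pixel in their window are NA.
#'
#' @param field an [OrientationField-class].
#' @param windowDiameter window diameter, pixels; odd (default 51).
#' @return An [AlignmentMap-class].
#' @export
alignmentMap <- function(field, windowDiameter = 51) {
  stopifnot(windowDiameter >= 1, windowDiameter %% 2 == 1)
  off <- diskOffsets(windowDiameter)
  v <- field@valid * 1
  th2 <- 2 * field@angle * pi / 180
  C <- windowSum(v * cos(th2), off)
  S_ <- windowSum(v * sin(th2), off)
  N <- windowSum(v, off)
  S <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- N > 0
  S[ok] <- sqrt(C[ok]^2 + S_[ok]^2) / N[ok]
  S[S > 1] <- 1                          # guard fp round-up
  new("AlignmentMap", S = S, windowDiameter = windowDiameter)
}

#' Per-cell alignment: mean statistic over MT pixels
#'
#' Arithmetic mean of the local alignment statistic over all microtubule
#' pixels of the cell; close to 1 when the network is locally parallel on
#' the window length scale, lower when filaments cross at diverse angles.
#'
#' @param map an [AlignmentMap-class].
#' @param mtMask logical MT mask selecting the averaged pixels.
#' @return scalar in [0, 1].
#' @export
cellAlignment <- function(map, mtMask) {
  sel <- mtMask & !is.na(map@S)
  if (!any(sel)) stop("no MT pixels to average")
  mean(map@S[sel])
}

#' Full orientation analysis of a binarised image
#'
#' @param mask logical MT mask.
#' @param elementLength,angleStep,windowDiameter see [orientationMap()]
#'   and [alignmentMap()].
#' @return list with \code{field}, \code{map} and the per-cell scalar
#'   \code{alignment}.
#' @export
analyzeOrientation <- function(mask, elementLength = 11, angleStep = 10,
                               windowDiameter = 51) {
  field <- orientationMap(mask, elementLength = elementLength,
                          angleStep = angleStep)
  map <- alignmentMap(field, windowDiameter = windowDiameter)
  list(field = field, map = map,
       alignment = cellAlignment(map, mask))
}
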