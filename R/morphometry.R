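## Microtubule-network morphometry: cell-area detection, top-hat
## enhancement, fixed-threshold binarisation, thinning, branch-point
## detection and the density metrics.

asMatrixImage <- function(x) {
  ## EBImage filters accept plain numeric matrices; keep matrix layout
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Detect the imaged cell area
#'
#' Coarse Gaussian smoothing, Otsu thresholding, hole filling and
#' selection of the largest connected foreground component. A constant
#' positive image yields the whole frame; an all-zero image is an empty
#' field.
#'
#' @param img a [FilamentImage-class].
#' @param smoothSigma Gaussian sigma, pixels (default 10; coarse enough
#'   to merge the filament texture into one blob).
#' @param fillHoles fill enclosed background holes (default TRUE).
#' @return A [CellMask-class].
#' @export
detectCellArea <- function(img, smoothSigma = 10, fillHoles = TRUE) {
  px <- pixels(img)
  if (max(px) <= 0) stop("empty field: no foreground signal")
  if (max(px) == min(px))                     # constant positive image
    return(CellMask(matrix(TRUE, nrow(px), ncol(px))))
  sm <- asMatrixImage(px)
  if (smoothSigma > 0) sm <- EBImage::gblur(sm, sigma = smoothSigma)
  rng <- range(sm)
  norm <- (sm - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > th
  if (!any(mask)) stop("empty field: no foreground after thresholding")
  if (all(mask)) return(CellMask(mask))
  m <- EBImage::Image(mask * 1)
  if (fillHoles) m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  labs <- as.integer(EBImage::imageData(lab))
  tab <- tabulate(labs[labs > 0])
  keep <- which.max(tab)
  out <- matrix(labs == keep, nrow(px), ncol(px))
  if (fillHoles) out <- EBImage::imageData(EBImage::fillHull(
    EBImage::Image(out * 1))) > 0
  CellMask(matrix(out, nrow(px), ncol(px)))
}

#' White top-hat filament enhancement
#'
#' Subtracts the morphological opening with a disk of the given radius
#' from the image, keeping structures thinner than the disk and zeroing
#' flat backgrounds. Output is clamped at zero and never exceeds the
#' input.
#'
#' @param img a [FilamentImage-class].
#' @param radius disk radius, pixels (default 5; must exceed the filament
#'   width and stay below the inter-filament spacing).
#' @return A [FilamentImage-class] of the enhanced signal.
#' @export
enhanceTophat <- function(img, radius = 5) {
  stopifnot(radius >= 1)
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  px <- asMatrixImage(pixels(img))
  opened <- EBImage::imageData(EBImage::opening(EBImage::Image(px), kern))
  out <- px - matrix(opened, nrow(px), ncol(px))
  out[out < 0] <- 0
  FilamentImage(out, pixelSize = pixelSize(img), id = imageId(img))
}

#' Fixed-threshold binarisation
#'
#' A pixel is foreground iff its intensity strictly exceeds the
#' threshold. The same configured threshold is meant to be applied to
#' every image of a run.
#'
#' @param img a [FilamentImage-class] or numeric matrix.
#' @param threshold finite intensity threshold.
#' @return logical matrix.
#' @export
binarize <- function(img, threshold) {
  stopifnot(is.finite(threshold))
  px <- if (is(img, "FilamentImage")) pixels(img) else as.matrix(img)
  px > threshold
}

#' Topology-preserving skeletonization
#'
#' Reduces a binary mask to a 1-px-wide, 8-connected skeleton by
#' two-subiteration parallel thinning (Guo-Hall). The skeleton is a
#' subset of the input and the operation is idempotent.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask))
  guoHallThin(mask)
}

#' Branch-point detection on a skeleton
#'
#' A branch pixel is a skeleton pixel with at least three skeleton
#' neighbours in 8-connectivity; 8-connected clusters of branch pixels
#' are merged and counted once (thinning can emit 2-px junction
#' clusters).
#'
#' @param skeleton logical matrix, 1-px-wide skeleton.
#' @return list with \code{count} (integer) and \code{mask} (logical
#'   matrix of branch pixels).
#' @export
detectBranchpoints <- function(skeleton) {
  stopifnot(is.logical(skeleton))
  bp <- skeleton & neighborCount(skeleton) >= 3
  list(count = countComponents8(bp), mask = bp)
}

#' Morphometry metrics for one cell
#'
#' Skeleton length is the skeleton pixel count; with
#' \code{diagonalWeight = TRUE} each pixel contributes the mean step
#' length of its geodesic neighbourhood (diagonal steps weighted sqrt(2))
#' instead. MT density is skeleton length over cell area; crossing
#' density is branch points over skeleton length and is flagged
#' undefined for an empty skeleton.
#'
#' @param mask a [CellMask-class] (area > 0).
#' @param skeleton logical skeleton matrix.
#' @param branchCount integer number of merged branch points (e.g. from
#'   [detectBranchpoints()]).
#' @param diagonalWeight logical; geodesic length weighting (default
#'   FALSE, plain pixel count).
#' @return A [MorphometryResult-class].
#' @export
measureMorphometry <- function(mask, skeleton, branchCount,
                               diagonalWeight = FALSE) {
  stopifnot(maskArea(mask) > 0)
  len <- if (!diagonalWeight) sum(skeleton) else geodesicLength(skeleton)
  dens <- len / maskArea(mask)
  defined <- len > 0
  bp <- detectBranchpoints(skeleton)
  new("MorphometryResult", skeleton = skeleton, branchMask = bp$mask,
      skeletonLength = len, branchpointCount = as.integer(branchCount),
      mtDensity = dens,
      crossingDensity = if (defined) branchCount / len else NA_real_,
      crossingDefined = defined)
}

## geodesic skeleton length: half-sum of step lengths to 8-neighbours
## (horizontal/vertical 1, diagonal sqrt(2)), isolated pixels count 1
geodesicLength <- function(skeleton) {
  m <- skeleton * 1
  straight <- matrix(0, nrow(m), ncol(m))
  diagonal <- straight
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- shiftMat(m, dr, dc, fill = 0)
    if (dr == 0 || dc == 0) straight <- straight + s else diagonal <- diagonal + s
  }
  per <- (straight + sqrt(2) * diagonal) / 2
  per[skeleton & per == 0] <- 1
  sum(per[skeleton])
}

#' Run the full morphometry chain on one image
#'
#' Top-hat enhancement, fixed-threshold binarisation (restricted to the
#' detected cell area), thinning, branch-point detection and metric
#' computation.
#'
#' @param img a [FilamentImage-class].
#' @param threshold manual intensity threshold applied uniformly per run.
#' @param tophatRadius top-hat disk radius, pixels.
#' @param smoothSigma cell-area smoothing sigma, pixels.
#' @param diagonalWeight see [measureMorphometry()].
#' @param cellMaskOverride optional [CellMask-class] to bypass detection
#'   (used when the full frame is the cell, e.g. synthetic benchmarks).
#' @return list with \code{result} ([MorphometryResult-class]),
#'   \code{mask} ([CellMask-class]) and \code{binary} (logical matrix).
#' @export
analyzeMorphometry <- function(img, threshold, tophatRadius = 5,
                               smoothSigma = 10, diagonalWeight = FALSE,
                               cellMaskOverride = NULL) {
  cm <- if (is.null(cellMaskOverride))
    detectCellArea(img, smoothSigma = smoothSigma) else cellMaskOverride
  enh <- enhanceTophat(img, radius = tophatRadius)
  bin <- binarize(enh, threshold) & cellMask(cm)
  skel <- skeletonize(bin)
  bp <- detectBranchpoints(skel)
  list(result = measureMorphometry(cm, skel, bp$count,
                                   diagonalWeight = diagonalWeight),
       mask = cm, binary = bin)
}
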