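## Synthetic filament-network generator. Filaments are straight lines
## clipped to the frame; ground truth (angles, centerline pixels, pairwise
## crossings, axial resultant length) is computed from the line geometry
## before any rendering, so blur/noise cannot alter it.

## run expr with a locally seeded RNG, restoring the caller's RNG state
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## parameter range t for which (row0 - t sin, col0 + t cos) stays in frame
clipLineToFrame <- function(row0, col0, angle, H, W) {
  th <- angle * pi / 180
  dr <- -sin(th); dc <- cos(th)
  tmin <- -Inf; tmax <- Inf
  for (ax in 1:2) {
    d <- if (ax == 1) dr else dc
    x0 <- if (ax == 1) row0 else col0
    hi <- if (ax == 1) H else W
    if (abs(d) < 1e-12) {
      if (x0 < 1 || x0 > hi) return(NULL)
    } else {
      t1 <- (1 - x0) / d; t2 <- (hi - x0) / d
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (!is.finite(tmin) || !is.finite(tmax) || tmin > tmax) return(NULL)
  c(tmin, tmax)
}

## integer centerline pixels along the clipped line, stepping the dominant axis
centerlinePixels <- function(row0, col0, angle, trange) {
  th <- angle * pi / 180
  dr <- -sin(th); dc <- cos(th)
  if (abs(dc) >= abs(dr)) {
    cA <- col0 + trange[1] * dc; cB <- col0 + trange[2] * dc
    cs <- seq(ceiling(min(cA, cB) - 1e-9), floor(max(cA, cB) + 1e-9))
    if (!length(cs)) return(matrix(integer(), 0, 2))
    t <- (cs - col0) / dc
    rs <- rnd(row0 + t * dr)
  } else {
    rA <- row0 + trange[1] * dr; rB <- row0 + trange[2] * dr
    rs <- seq(ceiling(min(rA, rB) - 1e-9), floor(max(rA, rB) + 1e-9))
    if (!length(rs)) return(matrix(integer(), 0, 2))
    t <- (rs - row0) / dr
    cs <- rnd(col0 + t * dc)
  }
  cbind(row = as.integer(rs), col = as.integer(cs))
}

#' Sample filament centre points and axial orientations
#'
#' Orientation modes: \code{"single_angle"} gives every filament the mean
#' angle; \code{"uniform_axial"} draws uniformly on [0, 180);
#' \code{"wrapped_dispersion"} draws doubled angles from a wrapped normal
#' with concentration \code{dispersion} (SD \code{1/sqrt(dispersion)} rad
#' on the doubled circle) and halves them, the sampling convention matched
#' to the angle-doubling analysis. \code{dispersion = 0} falls back to
#' uniform.
#'
#' @param spec a [NetworkSpec-class].
#' @return data.frame with columns \code{row}, \code{col}, \code{angle}
#'   (degrees in [0, 180)); deterministic given \code{spec}.
#' @export
sampleFilaments <- function(spec) {
  validObject(spec)
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  n <- spec@nFilaments
  withLocalSeed(spec@seed, {
    angle <- switch(spec@orientationMode,
      single_angle = rep(spec@meanAngle, n),
      uniform_axial = runif(n, 0, 180),
      wrapped_dispersion = {
        if (spec@dispersion == 0) runif(n, 0, 180) else {
          doubled <- rnorm(n, 2 * spec@meanAngle * pi / 180,
                           1 / sqrt(spec@dispersion))
          (doubled * 90 / pi) %% 180
        }
      })
    data.frame(row = runif(n, 1, H), col = runif(n, 1, W), angle = angle)
  })
}

#' Exact ground truth of a filament arrangement
#'
#' Counts pairwise intersections of the clipped centerlines inside the
#' frame (detector-independent), collects per-filament centerline pixels,
#' and computes the axial mean resultant length
#' \eqn{|n^{-1}\sum_j e^{2i\theta_j}|} of the angle population.
#'
#' @param filaments data.frame as from [sampleFilaments()].
#' @param imageSize integer c(H, W).
#' @return A [NetworkGroundTruth-class] object.
#' @export
networkTruth <- function(filaments, imageSize) {
  H <- imageSize[1]; W <- imageSize[2]
  n <- nrow(filaments)
  cl <- vector("list", n)
  tr <- vector("list", n)
  for (i in seq_len(n)) {
    trange <- clipLineToFrame(filaments$row[i], filaments$col[i],
                              filaments$angle[i], H, W)
    tr[[i]] <- trange
    cl[[i]] <- if (is.null(trange)) matrix(integer(), 0, 2) else
      centerlinePixels(filaments$row[i], filaments$col[i],
                       filaments$angle[i], trange)
  }
  crossings <- 0L
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (is.null(tr[[i]]) || is.null(tr[[j]])) next
    ti <- filaments$angle[i] * pi / 180; tj <- filaments$angle[j] * pi / 180
    di <- c(-sin(ti), cos(ti)); dj <- c(-sin(tj), cos(tj))
    det <- di[1] * (-dj[2]) - (-dj[1]) * di[2]
    if (abs(det) < 1e-9) next                      # parallel (axial)
    rhs <- c(filaments$row[j] - filaments$row[i],
             filaments$col[j] - filaments$col[i])
    s <- (rhs[1] * (-dj[2]) - (-dj[1]) * rhs[2]) / det
    t2 <- (di[1] * rhs[2] - rhs[1] * di[2]) / det
    if (s >= tr[[i]][1] && s <= tr[[i]][2] &&
        t2 >= tr[[j]][1] && t2 <= tr[[j]][2])
      crossings <- crossings + 1L
  }
  resultant <- if (n == 0) NA_real_ else
    Mod(mean(exp(2i * filaments$angle * pi / 180)))
  new("NetworkGroundTruth", angles = filaments$angle, centerlines = cl,
      centerlineLength = sum(vapply(cl, nrow, 0L)),
      crossingCount = crossings, resultantLength = resultant)
}

#' Render a filament arrangement to a noisy grayscale image
#'
#' Centerline pixels are dilated to the requested width with a digital
#' disk, blurred with a Gaussian kernel, scaled to unit amplitude, and
#' corrupted with a constant background plus additive Gaussian noise
#' (clamped at zero).
#'
#' @inheritParams networkTruth
#' @param spec a [NetworkSpec-class]; rendering parameters and noise seed
#'   are taken from it.
#' @param id identifier for the returned image.
#' @return A [FilamentImage-class].
#' @export
renderNetwork <- function(filaments, spec, id = "synthetic") {
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(filaments))) {
    trange <- clipLineToFrame(filaments$row[i], filaments$col[i],
                              filaments$angle[i], H, W)
    if (is.null(trange)) next
    px <- centerlinePixels(filaments$row[i], filaments$col[i],
                           filaments$angle[i], trange)
    mask[px] <- TRUE
  }
  r <- (spec@filamentWidth - 1) / 2
  if (r >= 1) mask <- binDilate(mask, diskOffsets(2 * floor(r) + 1))
  img <- mask * 1
  if (spec@blurSigma > 0) {
    img <- EBImage::gblur(img, sigma = spec@blurSigma)
    if (max(img) > 0) img <- img / max(img)
  }
  withLocalSeed(spec@seed + 1L, {
    img <- spec@backgroundLevel + img +
      matrix(rnorm(H * W, 0, spec@noiseSd), H, W)
  })
  img[img < 0] <- 0
  FilamentImage(img, id = id)
}

#' Generate a ground-truthed synthetic filament-network image
#'
#' Convenience wrapper: [sampleFilaments()], [networkTruth()] and
#' [renderNetwork()] under one seed. The ground truth is computed from
#' the line geometry before rendering.
#'
#' @param spec a [NetworkSpec-class].
#' @param id identifier for the image.
#' @return list with elements \code{image} ([FilamentImage-class]),
#'   \code{truth} ([NetworkGroundTruth-class]) and \code{filaments}
#'   (data.frame).
#' @examples
#' out <- generateFilamentImage(NetworkSpec(nFilaments = 5L, seed = 7L))
#' out$truth@resultantLength
#' @export
generateFilamentImage <- function(spec, id = "synthetic") {
  validObject(spec)
  filaments <- sampleFilaments(spec)
  list(image = renderNetwork(filaments, spec, id = id),
       truth = networkTruth(filaments, spec@imageSize),
       filaments = filaments)
}

#' Rotate a filament arrangement about the frame centre
#'
#' Exact rotation in line-parameter space (no pixel interpolation):
#' centres rotate about the frame midpoint and angles shift mod 180.
#' Useful for rotation-equivariance checks of the orientation analysis.
#'
#' @inheritParams networkTruth
#' @param delta rotation, degrees (counter-clockwise).
#' @return rotated filament data.frame.
#' @export
rotateFilaments <- function(filaments, delta, imageSize) {
  H <- imageSize[1]; W <- imageSize[2]
  cy <- (1 + H) / 2; cx <- (1 + W) / 2
  th <- delta * pi / 180
  ## x = col, y = -row for a CCW visual rotation in matrix convention
  x <- filaments$col - cx; y <- -(filaments$row - cy)
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  data.frame(row = cy - yr, col = cx + xr,
             angle = (filaments$angle + delta) %% 180)
}
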