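## Conversion of approach curves to force-indentation data and Young's
## modulus estimation by fitting the Sneddon sphere model at fixed
## indentation depths.

## linear baseline fitted to the leading fraction of samples (pre-contact)
fitBaseline <- function(z, d, fraction = 0.3, minSamples = 10) {
  n <- max(2L, floor(length(z) * fraction))
  if (n < minSamples)
    stop("baseline underdetermined: fewer than ", minSamples,
         " pre-contact samples")
  co <- coef(lm(d[seq_len(n)] ~ z[seq_len(n)]))
  list(intercept = co[[1]], slope = co[[2]], n = n)
}

#' Convert an approach curve to force-indentation data
#'
#' The cantilever bending is subtracted from the piezo travel to obtain
#' the indentation: after removing the fitted pre-contact baseline from
#' the deflection, \eqn{F = k d} and \eqn{\delta = (z - z_0) - d}.
#' Samples before the contact point (\eqn{\delta < 0}) are flagged.
#'
#' @param curve a [ForceCurve-class].
#' @param z0 contact point, nm; must lie inside the recorded z range.
#' @param baselineFraction leading fraction of samples used for the
#'   baseline line fit (default 0.3).
#' @param minBaseline minimum number of baseline samples (default 10).
#' @return An [IndentationCurve-class] (force in nN: N/m times nm).
#' @export
toForceIndentation <- function(curve, z0, baselineFraction = 0.3,
                               minBaseline = 10) {
  z <- curve@z; d <- curve@d
  if (z0 < min(z) || z0 > max(z)) stop("z0 outside the recorded z range")
  bl <- fitBaseline(z, d, baselineFraction, minBaseline)
  dc <- d - (bl$intercept + bl$slope * z)
  force <- curve@k * dc
  delta <- (z - z0) - dc
  new("IndentationCurve", delta = delta, force = force, z0 = z0,
      preContact = delta < 0)
}

## Sneddon force per unit modulus (nN per Pa) at indentation delta (nm)
sneddonShape <- function(delta, nu, Rs) {
  out <- numeric(length(delta))
  pos <- delta > 0
  if (any(pos)) out[pos] <- sneddonForce(delta[pos], E = 1, nu = nu, Rs = Rs)
  out
}

#' Fit the Sneddon sphere model to one approach curve
#'
#' Least squares over (E, z0). The fitted sample range runs from the
#' start of the curve (pre-contact baseline region, model force 0) up to
#' the sample where the indentation reaches \code{fitDepth}; within that
#' fixed range the residual is \eqn{F_{obs} - E\,\phi(\delta)} past
#' contact. E enters the model linearly, so for fixed z0 the optimal E
#' is the conditional least-squares solution; the contact point is then
#' found by a deterministic grid search over the allowed z0 range
#' refined by local minimisation. Because the fitted range itself
#' depends on the contact point, the range is initialised from the
#' first sample whose force exceeds max(3 x baseline noise SD, 1\% of
#' the peak force) and the fit is iterated to self-consistency (the
#' range is recomputed from the fitted z0 until stable). Both
#' parameters are bounded.
#'
#' @param curve a [ForceCurve-class].
#' @param fitDepth indentation window upper edge, nm (e.g. 200, 400,
#'   600).
#' @param eBounds bounds on E, Pa (default c(1, 1e6)).
#' @param z0Bounds bounds on z0, nm (default the recorded z range).
#' @param baselineFraction,minBaseline see [toForceIndentation()].
#' @param gridN number of z0 grid candidates (default 201).
#' @param minPoints minimum in-window samples for a valid fit (default
#'   10).
#' @param maxIter maximum window/fit self-consistency iterations
#'   (default 6).
#' @return A [HertzFitResult-class].
#' @export
fitHertz <- function(curve, fitDepth, eBounds = c(1, 1e6),
                     z0Bounds = NULL, baselineFraction = 0.3,
                     minBaseline = 10, gridN = 201, minPoints = 10,
                     maxIter = 6) {
  stopifnot(fitDepth > 0)
  z <- curve@z; d <- curve@d
  bl <- fitBaseline(z, d, baselineFraction, minBaseline)
  dc <- d - (bl$intercept + bl$slope * z)
  force <- curve@k * dc
  nu <- curve@nu; Rs <- curve@Rs
  if (is.null(z0Bounds)) z0Bounds <- range(z)

  ## initial contact estimate: first crossing of a noise-robust force
  ## threshold (3 sigma of the baseline residuals, floored at 1% of the
  ## peak force)
  nb <- max(2L, floor(length(z) * baselineFraction))
  sdF <- sd(force[seq_len(nb)])
  thr <- max(3 * sdF, 0.01 * max(force), 1e-12)
  cross <- which(force > thr)
  if (!length(cross)) stop("no contact detected: force never exceeds ",
                           "the baseline noise threshold")
  z0hat <- z[cross[1]]

  ## rss over a FIXED sample range `sel`, with E profiled out
  obj <- function(z0, sel) {
    delta <- (z[sel] - z0) - dc[sel]
    phi <- sneddonShape(delta, nu, Rs)
    den <- sum(phi^2)
    E <- if (den > 0) sum(force[sel] * phi) / den else eBounds[1]
    E <- min(max(E, eBounds[1]), eBounds[2])
    list(rss = sum((force[sel] - E * phi)^2), E = E)
  }

  z0 <- z0hat
  sel <- NULL
  for (iter in seq_len(maxIter)) {
    ## fitted range: curve start up to the depth-reaching sample
    delta <- (z - z0) - dc
    over <- which(delta > fitDepth)
    hi <- if (length(over)) over[1] else length(z)
    selNew <- seq_len(hi)
    if (sum(delta[selNew] >= 0 & delta[selNew] <= fitDepth) < minPoints)
      stop("fewer than ", minPoints, " in-range samples")
    if (!is.null(sel) && identical(selNew, sel)) break
    sel <- selNew
    lo <- max(z0Bounds[1], min(z))
    up <- min(z0Bounds[2], z[hi])
    grid <- seq(lo, up, length.out = gridN)
    vals <- vapply(grid, function(g) obj(g, sel)$rss, 0)
    ## the landscape can be multimodal at shallow depths (E compensates
    ## for contact-point error): refine every local minimum of the grid
    ## and keep the best refined candidate
    n <- length(vals)
    isMin <- vals <= c(Inf, vals[-n]) & vals <= c(vals[-1], Inf)
    cand <- order(vals)[order(vals) %in% which(isMin)]
    cand <- utils::head(cand, 8L)
    bestZ <- grid[cand[1]]; bestV <- vals[cand[1]]
    for (i in cand) {
      gl <- grid[max(1, i - 1)]; gu <- grid[min(n, i + 1)]
      opt <- optimize(function(g) obj(g, sel)$rss, c(gl, gu), tol = 1e-7)
      if (opt$objective < bestV) {
        bestV <- opt$objective; bestZ <- opt$minimum
      }
    }
    z0 <- bestZ
  }
  fin <- obj(z0, sel)
  deltaFin <- (z[sel] - z0) - dc[sel]
  nwin <- sum(deltaFin >= 0 & deltaFin <= fitDepth)
  new("HertzFitResult", E = fin$E, z0 = z0, fitDepth = fitDepth,
      rmsResidual = sqrt(fin$rss / length(sel)),
      nPoints = as.integer(nwin), status = "ok")
}

#' Batch Sneddon fitting over curves and depths
#'
#' One fit per curve per depth; individual failures are recorded in the
#' status column rather than aborting the batch. Per-cell aggregation
#' (median E per depth over the 8-10 curves of a cell) is available via
#' \code{aggregate = TRUE} when \code{cellIds} are supplied.
#'
#' @param curves list of [ForceCurve-class] objects (non-empty).
#' @param depths indentation depths, nm (default c(200, 400, 600)).
#' @param cellIds optional character vector mapping curves to cells.
#' @param aggregate if TRUE also return the per-cell median-E table as
#'   attribute \code{"cells"}.
#' @param summaryFun per-cell summary (default [median]; mean available).
#' @param ... passed to [fitHertz()].
#' @return data.frame with columns curve_id, cell_id, depth_nm, E_Pa,
#'   z0_nm, rms_nN, n_points, status.
#' @export
batchFit <- function(curves, depths = c(200, 400, 600), cellIds = NULL,
                     aggregate = !is.null(cellIds), summaryFun = median,
                     ...) {
  if (!length(curves)) stop("empty curve list")
  if (is.null(cellIds)) cellIds <- rep(NA_character_, length(curves))
  rows <- list()
  for (i in seq_along(curves)) {
    cid <- curves[[i]]@id
    for (dep in depths) {
      r <- tryCatch({
        f <- fitHertz(curves[[i]], fitDepth = dep, ...)
        data.frame(curve_id = cid, cell_id = cellIds[i], depth_nm = dep,
                   E_Pa = f@E, z0_nm = f@z0, rms_nN = f@rmsResidual,
                   n_points = f@nPoints, status = f@status)
      }, error = function(e)
        data.frame(curve_id = cid, cell_id = cellIds[i], depth_nm = dep,
                   E_Pa = NA_real_, z0_nm = NA_real_, rms_nN = NA_real_,
                   n_points = NA_integer_,
                   status = paste0("error: ", conditionMessage(e))))
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (aggregate && any(!is.na(cellIds))) {
    ok <- out[out$status == "ok" & !is.na(out$cell_id), ]
    cells <- stats::aggregate(E_Pa ~ cell_id + depth_nm, data = ok,
                              FUN = summaryFun)
    attr(out, "cells") <- cells[order(cells$cell_id, cells$depth_nm), ]
  }
  out
}
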