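## Forward model of an AFM approach curve from the Sneddon sphere force.

## noiseless contact deflection: solve k d = F((z - z0) - d) for each z
## past contact. g(d) = k d - F(s - d) is strictly increasing with
## g(0) <= 0 <= g(s), so the root is unique; vectorised Newton with
## bisection safeguard, relative tolerance 1e-10.
solveContactDeflection <- function(s, E, nu, k, Rs) {
  if (!length(s)) return(numeric())
  lo <- rep(0, length(s)); hi <- s
  d <- 0.5 * s
  for (it in 1:200) {
    delta <- s - d
    Fd <- sneddonForce(delta, E, nu, Rs)
    g <- k * d - Fd
    lo[g < 0] <- d[g < 0]
    hi[g > 0] <- d[g > 0]
    ## dF/ddelta = (dF/da) / (ddelta/da), evaluated at the current delta
    a <- sneddonContactRadius(delta, Rs)
    L <- ifelse(a > 0, log((Rs + a) / (Rs - a)), 0)
    dFda <- (E / (1 - nu^2)) * ifelse(a > 0,
      a * L + (a^2 + Rs^2) / 2 * 2 * Rs / (Rs^2 - a^2) - Rs, 0) * 1e-9
    dDda <- ifelse(a > 0, L / 2 + a * Rs / (Rs^2 - a^2), 1)
    gp <- k + ifelse(a > 0, dFda / dDda,
                     k)               # flat slope at the contact edge
    dn <- d - g / gp
    bad <- dn <= lo | dn >= hi | !is.finite(dn)
    dn[bad] <- (lo[bad] + hi[bad]) / 2
    done <- abs(dn - d) <= 1e-10 * pmax(dn, 1e-6)
    d <- dn
    if (all(done)) break
  }
  d
}

#' Generate a synthetic AFM approach curve
#'
#' Samples piezo positions on the configured grid. Below the contact
#' point the deflection is the linear baseline; beyond it the deflection
#' solves the implicit self-consistency \eqn{d = F(\delta)/k} with
#' \eqn{\delta = (z - z_0) - d} and \eqn{F} the Sneddon sphere force, so
#' a noiseless curve and the fitting model are exactly consistent.
#' Gaussian noise of SD \code{deflectionNoiseSd} is added to the
#' deflection.
#'
#' @param spec a [CurveSpec-class].
#' @param id identifier for the returned curve.
#' @return A [ForceCurve-class]; the generating parameters (E, z0) are
#'   attached as attributes \code{"E"} and \code{"z0"} for round-trip
#'   tests.
#' @examples
#' fc <- generateForceCurve(CurveSpec(deflectionNoiseSd = 0))
#' @export
generateForceCurve <- function(spec, id = "curve") {
  validObject(spec)
  z <- seq(spec@zRange[1], spec@zRange[2], by = spec@zStep)
  if ((spec@zRange[2] - spec@contactPoint) >= spec@beadRadius)
    stop("requested z range drives indentation beyond the bead radius")
  base <- spec@baselineSlope * (z - z[1])
  d <- base
  past <- z > spec@contactPoint
  if (any(past))
    d[past] <- d[past] + solveContactDeflection(
      z[past] - spec@contactPoint, spec@youngsModulus, spec@poissonRatio,
      spec@springConstant, spec@beadRadius)
  if (spec@deflectionNoiseSd > 0)
    d <- withLocalSeed(spec@seed,
                       d + rnorm(length(d), 0, spec@deflectionNoiseSd))
  fc <- ForceCurve(z, d, k = spec@springConstant, Rs = spec@beadRadius,
                   nu = spec@poissonRatio, id = id)
  attr(fc, "E") <- spec@youngsModulus
  attr(fc, "z0") <- spec@contactPoint
  fc
}
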