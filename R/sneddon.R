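#' Sneddon rigid-sphere contact model
#'
#' Parametric solution for a rigid sphere of radius \code{Rs} indenting an
#' elastic half-space, parametrised by the contact radius \code{a}:
#' \deqn{F(a) = \frac{E}{1-\nu^2}\left[\frac{a^2+R_s^2}{2}
#'   \ln\frac{R_s+a}{R_s-a} - a R_s\right], \qquad
#'   \delta(a) = \frac{a}{2}\ln\frac{R_s+a}{R_s-a}.}
#' For small indentations (\eqn{\delta/R_s \lesssim 0.005}) this reduces to
#' the Hertz expression \eqn{F = (4/3)\,E/(1-\nu^2)\,\sqrt{R_s}\,
#' \delta^{3/2}}.
#'
#' \code{sneddonIndentation} evaluates \eqn{\delta(a)};
#' \code{sneddonContactRadius} inverts it (the map is strictly increasing
#' on \eqn{(0, R_s)}, so the inverse is unique) and \code{sneddonForce}
#' composes the two to give the force at a prescribed indentation.
#'
#' Lengths are in nm, \code{E} in Pa; forces are returned in nN.
#'
#' @param a contact radius, nm, in [0, Rs).
#' @param delta indentation depth, nm (vectorised, each >= 0).
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio (0.5 for cells).
#' @param Rs sphere radius, nm.
#' @return \code{sneddonIndentation}: indentation nm;
#'   \code{sneddonContactRadius}: contact radius nm;
#'   \code{sneddonForce}: force nN.
#' @examples
#' sneddonIndentation(225, Rs = 2250)    # 22.575 nm; Hertz limit a^2/Rs = 22.5
#' sneddonForce(10, E = 1000, nu = 0.5, Rs = 2250)  # ~2.67e-3 nN (2.67 pN)
#' @name sneddon
NULL

#' @rdname sneddon
#' @export
sneddonIndentation <- function(a, Rs) {
  stopifnot(all(a >= 0), all(a < Rs))
  ifelse(a == 0, 0, (a / 2) * log((Rs + a) / (Rs - a)))
}

#' @rdname sneddon
#' @export
sneddonContactRadius <- function(delta, Rs) {
  if (any(delta < 0)) stop("indentation must be >= 0")
  if (any(delta >= Rs)) stop("indentation out of model range")
  a <- numeric(length(delta))
  act <- delta > 0
  if (!any(act)) return(a)
  d <- delta[act]
  ## safeguarded Newton on delta(a) - d, bracket (0, Rs); converged
  ## elements are frozen so later iterations cannot disturb them
  lo <- rep(0, length(d))
  hi <- rep(Rs * (1 - 1e-12), length(d))
  x <- pmin(sqrt(d * Rs), 0.95 * Rs)     # Hertz-limit initial guess
  live <- rep(TRUE, length(d))
  for (it in 1:200) {
    xi <- x[live]; di <- d[live]
    L <- log((Rs + xi) / (Rs - xi))
    f <- (xi / 2) * L - di
    li <- lo[live]; hi2 <- hi[live]
    li[f < 0] <- xi[f < 0]
    hi2[f > 0] <- xi[f > 0]
    fp <- L / 2 + xi * Rs / (Rs^2 - xi^2)
    xn <- xi - f / fp
    bad <- xn < li | xn > hi2 | !is.finite(xn)
    xn[bad] <- (li[bad] + hi2[bad]) / 2
    done <- abs(f) <= 1e-13 * pmax(di, 1) | (hi2 - li) <= 1e-13 * Rs
    lo[live] <- li; hi[live] <- hi2; x[live] <- xn
    live[live] <- !done
    if (!any(live)) break
  }
  a[act] <- x
  a
}

#' @rdname sneddon
#' @export
sneddonForce <- function(delta, E, nu = 0.5, Rs) {
  stopifnot(E > 0, nu >= 0, nu <= 0.5, Rs > 0)
  a <- sneddonContactRadius(delta, Rs)
  bracket <- ifelse(a == 0, 0,
                    ((a^2 + Rs^2) / 2) * log((Rs + a) / (Rs - a)) - a * Rs)
  ## Pa * nm^2 = 1e-18 N = 1e-9 nN
  (E / (1 - nu^2)) * bracket * 1e-9
}

#' Hertz small-indentation closed form
#'
#' \eqn{F = (4/3)\,E/(1-\nu^2)\,\sqrt{R_s}\,\delta^{3/2}}, the paraboloid
#' limit of the sphere model; used as an independent check of
#' \code{\link{sneddonForce}} at shallow indentation.
#'
#' @inheritParams sneddonForce
#' @return force, nN.
#' @export
hertzForce <- function(delta, E, nu = 0.5, Rs) {
  (4 / 3) * (E / (1 - nu^2)) * sqrt(Rs) * delta^1.5 * 1e-9
}
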