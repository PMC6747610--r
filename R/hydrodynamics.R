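## Hydrodynamics: Stokes-Einstein relation, DLS scattering vector and
## cumulant analysis of intensity autocorrelation traces.

#' Stokes-Einstein relation
#'
#' \deqn{D = \frac{k_B T}{6 \pi \eta R}}
#'
#' @param radius hydrodynamic radius (m).
#' @param temperature K.
#' @param viscosity Pa s.
#' @return translational diffusion coefficient (m^2/s).
#' @examples
#' stokesEinstein(2.1e-9)  # ~1.17e-10 m^2/s
#' @export
stokesEinstein <- function(radius, temperature = 298.15,
                           viscosity = 8.872e-4) {
  stopifnot(radius > 0, temperature > 0, viscosity > 0)
  .constants$kB * temperature / (6 * pi * viscosity * radius)
}

#' Hydrodynamic radius from the diffusion coefficient
#'
#' Exact inverse of \code{\link{stokesEinstein}}.
#'
#' @param d diffusion coefficient (m^2/s).
#' @param temperature K.
#' @param viscosity Pa s.
#' @return hydrodynamic radius (m).
#' @export
radiusFromD <- function(d, temperature = 298.15, viscosity = 8.872e-4) {
  stopifnot(d > 0, temperature > 0, viscosity > 0)
  .constants$kB * temperature / (6 * pi * viscosity * d)
}

#' DLS scattering vector magnitude
#'
#' \deqn{q = \frac{4\pi n \sin(\theta/2)}{\lambda}}
#'
#' @param wavelength laser wavelength (m).
#' @param refractiveIndex solvent refractive index.
#' @param angle scattering angle (degrees), in (0, 180].
#' @return q in m^-1.
#' @export
scatteringVector <- function(wavelength = 633e-9, refractiveIndex = 1.333,
                             angle = 173) {
  stopifnot(angle > 0, angle <= 180, wavelength > 0)
  4 * pi * refractiveIndex * sin(angle * pi / 360) / wavelength
}

#' Cumulant analysis of a DLS autocorrelation trace
#'
#' The field autocorrelation is recovered through the Siegert relation
#' with unit coherence factor, \eqn{g_1 = \sqrt{g_2 - 1}}, and its
#' logarithm is fit to \eqn{\ln g_1(\tau) = b_0 - \Gamma\tau}
#' (order 1) or \eqn{b_0 - \Gamma\tau + \mu_2\tau^2/2} (order 2, the
#' default, robust to mild polydispersity). Then \eqn{D = \Gamma/q^2}
#' and the polydispersity index is \eqn{\mu_2/\Gamma^2}. The intercept
#' absorbs the overall amplitude, so the estimate is invariant to
#' scaling of \eqn{g_2 - 1}.
#'
#' @param meas a \linkS4class{DlsMeasurement} with >= 10 usable lags.
#' @param order 1 or 2.
#' @param minFraction lags with \code{g2Minus1} below this fraction of
#'   the maximum are dropped before the log transform (default 1e-3).
#' @return list with \code{D} (m^2/s), \code{D_cm2_s} (the same in
#'   cm^2/s), \code{gamma} (s^-1), \code{polydispersity}, \code{radius}
#'   (m), \code{q} (m^-1).
#' @export
cumulantFit <- function(meas, order = 2, minFraction = 1e-3) {
  stopifnot(order %in% c(1, 2))
  g2 <- meas@g2Minus1; tau <- meas@lagTimes
  keep <- is.finite(g2) & g2 > minFraction * max(g2, na.rm = TRUE)
  if (sum(keep) < 10L)
    stop("fewer than 10 usable lag points above the threshold")
  tau <- tau[keep]; g2 <- g2[keep]
  lg1 <- 0.5 * log(g2)
  if (stats::cor(tau, lg1) >= 0)
    stop("trace does not decay; cumulant fit not meaningful")
  ## weights ~ g2-1: the log transform inflates noise in the tail
  w <- g2
  fit <- if (order == 1) stats::lm(lg1 ~ tau, weights = w)
         else stats::lm(lg1 ~ tau + I(tau^2), weights = w)
  cf <- stats::coef(fit)
  gamma <- -cf[["tau"]]
  mu2 <- if (order == 2) 2 * cf[["I(tau^2)"]] else 0
  if (gamma <= 0) stop("non-positive decay rate; fit failed")
  q <- scatteringVector(meas@wavelength, meas@refractiveIndex, meas@angle)
  D <- gamma / q^2
  list(D = D, D_cm2_s = D * 1e4, gamma = gamma,
       polydispersity = mu2 / gamma^2,
       radius = radiusFromD(D, meas@temperature, meas@viscosity), q = q)
}
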