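#' Physical constants for blood
#'
#' Blood is treated as an incompressible Newtonian fluid. Defaults are the
#' values standard for large-vessel haemodynamics: dynamic viscosity
#' 0.004 Pa s and density 1060 kg/m^3.
#'
#' @param mu Dynamic viscosity (Pa s), strictly positive.
#' @param rho Density (kg/m^3), strictly positive.
#' @return An object of class `blood_properties` (a list with `mu`, `rho`).
#' @export
#' @examples
#' blood_properties()
blood_properties <- function(mu = 0.004, rho = 1060) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("'mu' must be a single positive number")
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("'rho' must be a single positive number")
  }
  structure(list(mu = mu, rho = rho), class = "blood_properties")
}

# conversion constant, fixed throughout the package
.MMHG_PA <- 133.322

#' Pressure unit conversions
#'
#' Fixed conversion 1 mmHg = 133.322 Pa. All internal computation is SI
#' (pascals); mmHg appears only at reporting boundaries.
#'
#' @param x Pressure values to convert.
#' @return Converted numeric vector.
#' @export
mmHg_to_Pa <- function(x) x * .MMHG_PA

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / .MMHG_PA

# trapezoid quadrature weights for possibly non-uniform abscissae
.trapz_weights <- function(t) {
  n <- length(t)
  if (n < 2L) stop("need at least two samples for quadrature")
  w <- numeric(n)
  dt <- diff(t)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dt[-(n - 1L)] + dt[-1L]) / 2
  w
}
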