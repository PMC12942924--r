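# Laser beam profiles on the irradiated (top) surface. Beams propagate along
# -z (normal incidence); the profile gives the surface irradiance P0(r).

#' Flat (top-hat) beam profile
#'
#' @param irradiance Constant irradiance inside the beam, W m^-2.
#' @param radius Beam radius, meters.
#' @return A `beam_profile` object.
#' @export
beam_flat <- function(irradiance, radius) {
  stopifnot(irradiance >= 0, radius > 0)
  structure(list(kind = "flat", peak = irradiance, radius = radius,
                 power = irradiance * pi * radius^2,
                 direction = c(0, -1)),
            class = "beam_profile")
}

#' Gaussian beam profile
#'
#' The irradiance is \eqn{P_0(r) = I_0 \exp(-2 r^2 / w^2)} with `w` the 1/e^2
#' waist radius. Specify the width either as `waist` (w directly) or as
#' `fwhm` (full-width at half-maximum of the irradiance profile,
#' \eqn{w = \mathrm{FWHM}/\sqrt{2\ln 2}}), and the amplitude either as `peak`
#' irradiance or total beam `power` (then \eqn{I_0 = 2P/(\pi w^2)} so that
#' \eqn{\int_0^\infty P_0(r)\, 2\pi r\, dr = P}).
#'
#' @param power Total beam power in W (alternative to `peak`).
#' @param peak Peak irradiance in W m^-2 (alternative to `power`).
#' @param fwhm Full-width at half-maximum in meters (alternative to `waist`).
#' @param waist 1/e^2 radius in meters (alternative to `fwhm`).
#' @return A `beam_profile` object.
#' @examples
#' beam_gaussian(power = 1.1, fwhm = 7e-3)
#' @export
beam_gaussian <- function(power = NULL, peak = NULL, fwhm = NULL, waist = NULL) {
  if (is.null(fwhm) == is.null(waist))
    stop("specify exactly one of fwhm or waist")
  w <- if (!is.null(waist)) waist else fwhm / sqrt(2 * log(2))
  stopifnot(w > 0)
  if (is.null(power) == is.null(peak))
    stop("specify exactly one of power or peak")
  if (is.null(peak)) peak <- 2 * power / (pi * w^2)
  if (is.null(power)) power <- peak * pi * w^2 / 2
  structure(list(kind = "gaussian", peak = peak, waist = w, power = power,
                 direction = c(0, -1)),
            class = "beam_profile")
}

#' Surface irradiance of a beam at radius r
#'
#' @param beam A `beam_profile`.
#' @param r Radial coordinate(s), meters (>= 0).
#' @return Irradiance P0(r) in W m^-2.
#' @export
surface_irradiance <- function(beam, r) {
  stopifnot(inherits(beam, "beam_profile"), all(r >= 0))
  switch(beam$kind,
    flat = ifelse(r <= beam$radius, beam$peak, 0),
    gaussian = beam$peak * exp(-2 * r^2 / beam$waist^2),
    stop("unknown beam kind"))
}

#' @exportS3Method base::print
print.beam_profile <- function(x, ...) {
  if (x$kind == "flat")
    cat(sprintf("flat beam: %g W/m^2 inside r <= %g m (power %.4g W)\n",
                x$peak, x$radius, x$power))
  else
    cat(sprintf("Gaussian beam: peak %g W/m^2, waist %g m (power %.4g W)\n",
                x$peak, x$waist, x$power))
  invisible(x)
}
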