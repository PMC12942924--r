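# Per-region optical properties and every derived coefficient used by the
# Beer-Lambert, standard-diffusion (SDA) and delta-P1 light models.

#' Optical properties of a medium
#'
#' @param mu_a Absorption coefficient, m^-1 (>= 0).
#' @param mu_s Scattering coefficient, m^-1 (>= 0).
#' @param g Scattering anisotropy factor (mean cosine), `0 <= g < 1`.
#' @param n Tissue-to-air refractive index ratio (> 0); the index mismatch is
#'   applied only at the air-tissue surface.
#' @return An `optical_properties` object.
#' @export
optical_properties <- function(mu_a, mu_s, g = 0, n = 1.33) {
  if (mu_a < 0 || mu_s < 0) stop("mu_a and mu_s must be non-negative")
  if (g < 0 || g >= 1) stop("anisotropy g must lie in [0, 1)")
  if (n <= 0) stop("refractive index ratio n must be positive")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' @exportS3Method base::print
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %g /m, mu_s = %g /m, g = %g, n = %g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

#' Derive every transport coefficient from raw optical properties
#'
#' Computes the reduced scattering coefficient \eqn{\mu_s' = (1-g)\mu_s}, the
#' delta-Eddington split of the phase function into a forward delta spike of
#' weight \eqn{f = g^2} plus a smooth part with moment \eqn{g^* = g/(1+g)} and
#' scattering \eqn{\mu_s^* = (1-f)\mu_s}, the transport coefficient
#' \eqn{\mu_{tr} = \mu_a + \mu_s'}, total \eqn{\mu_t^* = \mu_a + \mu_s^*},
#' effective attenuation \eqn{\mu_{eff} = \sqrt{3\mu_a\mu_{tr}}}, the SDA
#' diffusion coefficient \eqn{D = 1/(3(\mu_a+\mu_s'))}, the delta-P1 boundary
#' coefficient \eqn{h = 2/(3\mu_{tr})}, and the Fresnel reflection parameter
#' `A` from the refractive index ratio.
#'
#' Note the two distinct "starred" scattering coefficients: the SDA diffusion
#' coefficient uses the reduced coefficient \eqn{\mu_s'}, while the delta-P1
#' equations use the delta-Eddington \eqn{\mu_s^* = (1-g^2)\mu_s}.
#'
#' @param props An [optical_properties()] object.
#' @return A `derived_optics` object (all coefficients in SI units).
#' @examples
#' derive_optics(optical_properties(mu_a = 2, mu_s = 176, g = 0))
#' @export
derive_optics <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  if (props$mu_a == 0 && props$mu_s == 0)
    stop("degenerate medium: mu_a = mu_s = 0 leaves D undefined")
  g <- props$g
  mu_s_red  <- (1 - g) * props$mu_s
  f         <- g^2
  g_star    <- g / (1 + g)
  mu_s_star <- (1 - f) * props$mu_s
  mu_tr     <- props$mu_a + mu_s_red
  mu_t_star <- props$mu_a + mu_s_star
  mu_eff    <- sqrt(3 * props$mu_a * mu_tr)
  structure(list(
    mu_a = props$mu_a, mu_s = props$mu_s, g = g, n = props$n,
    mu_s_red = mu_s_red, f = f, g_star = g_star, mu_s_star = mu_s_star,
    mu_tr = mu_tr, mu_t_star = mu_t_star, mu_eff = mu_eff,
    D = 1 / (3 * mu_tr), h_opt = 2 / (3 * mu_tr),
    A = fresnel_A(props$n)
  ), class = "derived_optics")
}

#' @exportS3Method base::print
print.derived_optics <- function(x, ...) {
  cat(sprintf(
    "derived optics: mu_s' = %g, mu_s* = %g, mu_tr = %g, mu_t* = %g, mu_eff = %g /m\n",
    x$mu_s_red, x$mu_s_star, x$mu_tr, x$mu_t_star, x$mu_eff))
  cat(sprintf("  D = %.6g m, h = %.6g m, A = %.4f (n = %g)\n",
              x$D, x$h_opt, x$A, x$n))
  invisible(x)
}

#' Fresnel internal-reflection parameter A
#'
#' Cubic-polynomial fit of the boundary parameter encoding internal reflection
#' at a refractive-index-mismatched surface (from numerical integration of the
#' Fresnel reflection moments over a normal slab),
#' \deqn{A = -0.13755 n^3 + 4.3390 n^2 - 4.90466 n + 1.6896,}
#' where `n` is the tissue-to-air index ratio. `A(1)` is 1 to within the fit
#' tolerance (matched indices, no internal reflection); A increases with the
#' mismatch over the fitted range n in [1.0, 1.6].
#'
#' @param n Tissue-to-air refractive index ratio.
#' @return The dimensionless A coefficient. Values of `n` outside the fitted
#'   range trigger a warning but are still evaluated.
#' @export
fresnel_A <- function(n) {
  if (any(n <= 0)) stop("refractive index ratio must be positive")
  if (any(n < 1 - 1e-9 | n > 1.6 + 1e-9))
    warning("fresnel_A: n outside the fitted range [1.0, 1.6]; ",
            "extrapolating the cubic fit")
  -0.13755 * n^3 + 4.3390 * n^2 - 4.90466 * n + 1.6896
}

#' Scale optical properties linearly with relative nanoparticle concentration
#'
#' Linear interpolation of the absorption and scattering coefficients between
#' an unloaded base medium (0 %) and the nanoparticle-loaded reference medium
#' (100 %); anisotropy and refractive index are taken from the loaded medium.
#' Concentrations above 100 % extrapolate the same line.
#'
#' @param base [optical_properties()] of the unloaded medium (0 %).
#' @param loaded [optical_properties()] of the reference loaded medium (100 %).
#' @param c_rel Relative concentration in percent (>= 0).
#' @return An [optical_properties()] object at concentration `c_rel`.
#' @examples
#' gel <- optical_properties(2, 176, g = 0, n = 1.33)
#' gnp <- optical_properties(31, 289, g = 0, n = 1.33)
#' scale_with_concentration(gel, gnp, 50)  # mu_a = 16.5, mu_s = 232.5
#' @export
scale_with_concentration <- function(base, loaded, c_rel) {
  stopifnot(inherits(base, "optical_properties"),
            inherits(loaded, "optical_properties"))
  if (c_rel < 0) stop("relative concentration must be non-negative")
  w <- c_rel / 100
  optical_properties(
    mu_a = base$mu_a + w * (loaded$mu_a - base$mu_a),
    mu_s = base$mu_s + w * (loaded$mu_s - base$mu_s),
    g = loaded$g, n = loaded$n
  )
}

# helper: named list of derived_optics for a set of regions
derive_optics_map <- function(props_map) {
  stopifnot(is.list(props_map), !is.null(names(props_map)))
  lapply(props_map, function(p)
    if (inherits(p, "derived_optics")) p else derive_optics(p))
}

# per-triangle lookup of one derived coefficient
tri_optic <- function(mesh, optics, what) {
  optics <- derive_optics_map(optics)
  miss <- setdiff(unique(mesh$cell_region), names(optics))
  if (length(miss))
    stop("missing optical properties for region(s): ", paste(miss, collapse = ", "))
  vapply(optics, `[[`, numeric(1), what)[mesh$cell_region]
}
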