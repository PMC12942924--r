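# Analytical delta-P1 solution for a homogeneous semi-infinite medium under
# Gaussian-beam irradiation, built the classical way: Hankel transform in the
# radial coordinate, closed-form 1D solution per spatial frequency, numerical
# inverse transform. Serves as the independent reference for the FEM solver.

#' On-axis delta-P1 fluence in a semi-infinite medium (analytical)
#'
#' For a homogeneous half-space \eqn{z \ge 0} (z measured into the medium)
#' irradiated at normal incidence by a Gaussian beam of 1/e^2 waist `r0` and
#' peak irradiance `E0`, the collimated component is
#' \eqn{\phi_c = E_0 e^{-2r^2/r_0^2} e^{-\mu_t^* z}} and the diffuse
#' component satisfies, per radial spatial frequency k (zeroth-order Hankel
#' transform),
#' \deqn{\hat\phi_d'' - (\mu_{eff}^2 + k^2)\hat\phi_d = -Q \hat\phi_c,\quad
#'       Q = 3\mu_s^*(\mu_{tr} + g^*\mu_t^*),}
#' with the conservation condition
#' \eqn{\hat\phi_d - A h\, \hat\phi_d'(0) = -3 A h g^* \mu_s^* \hat\phi_c(0)}.
#' The particular + homogeneous solution is evaluated in a cancellation-free
#' form and inverted on the axis by adaptive quadrature over k.
#'
#' @param optics A `derived_optics` object (homogeneous medium).
#' @param r0 Beam 1/e^2 waist radius, meters.
#' @param E0 Peak surface irradiance, W m^-2.
#' @param z Depths below the surface, meters (vector).
#' @param A Fresnel boundary parameter; defaults to the one in `optics`.
#' @return `data.frame(z, phi_c, phi_d, phi)` with on-axis (r = 0) values.
#' @export
deltap1_semi_infinite <- function(optics, r0, E0, z, A = optics$A) {
  stopifnot(inherits(optics, "derived_optics"), r0 > 0, all(z >= 0))
  mt  <- optics$mu_t_star
  mtr <- optics$mu_tr
  meff <- optics$mu_eff
  Q <- 3 * optics$mu_s_star * (mtr + optics$g_star * mt)
  al <- A * optics$h_opt                      # A h
  G  <- 3 * al * optics$g_star * optics$mu_s_star
  Ck <- function(k) E0 * r0^2 / 4 * exp(-k^2 * r0^2 / 8)

  phi_d_hat <- function(k, zz) {
    nu <- sqrt(meff^2 + k^2)
    C <- Ck(k)
    s <- nu - mt
    # P (e^{-mt z} - e^{-nu z}) written via expm1 to survive nu -> mt
    term1 <- Q * C / (nu + mt) * (-expm1(-s * zz) / ifelse(s == 0, 1, s)) *
      exp(-mt * zz)
    term1[s == 0] <- (Q * C / (nu + mt) * zz * exp(-mt * zz))[s == 0]
    pb <- (Q * C * al / (nu + mt) - G * C) / (1 + al * nu)   # P + B
    term1 + pb * exp(-nu * zz)
  }
  kmax <- 30 / r0   # the Gaussian factor exp(-k^2 r0^2/8) is ~1e-49 there
  phi_d <- vapply(z, function(zz)
    stats::integrate(function(k) k * phi_d_hat(k, zz), 0, kmax,
                     rel.tol = 1e-9, abs.tol = 0, subdivisions = 400L)$value,
    numeric(1))
  phi_c <- E0 * exp(-mt * z)
  data.frame(z = z, phi_c = phi_c, phi_d = phi_d, phi = phi_c + phi_d)
}
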