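# Standard diffusion approximation (SDA) for the total fluence rate.
#
# Strong form: -div(D grad(phi)) + mu_a phi = S, with the laser entering
# through the partial-current (Robin) condition on the illuminated surface,
#   phi + 2 A D dphi/dn = 4 P0(r)    (outward normal),
# i.e. (1/(2A)) phi + D dphi/dn = (2/A) P0. Non-illuminated exterior
# boundaries get the homogeneous variant (P0 = 0) or, optionally, a zero-flux
# condition. The axis is a natural symmetry boundary.

#' Solve the standard diffusion approximation
#'
#' @param mesh A `ptt_mesh` with regions assigned.
#' @param optics Named list (one entry per region) of [optical_properties()]
#'   or [derive_optics()] objects.
#' @param beam A [beam_flat()] / [beam_gaussian()] profile applied on the
#'   `top` boundary.
#' @param lateral_bc Condition on the non-illuminated exterior boundaries
#'   (`right`, `bottom`): `"robin"` (homogeneous partial-current, default) or
#'   `"zero_flux"`.
#' @param source Optional volumetric source S (scalar, per-region named, or
#'   per-triangle), W m^-3; zero by default as the laser enters through the
#'   boundary condition.
#' @return A `scalar_field` with the fluence rate phi, W m^-2.
#' @export
solve_sda <- function(mesh, optics, beam, lateral_bc = c("robin", "zero_flux"),
                      source = 0) {
  lateral_bc <- match.arg(lateral_bc)
  if (!any(mesh$edges$tag == "top"))
    stop("mesh has no 'top' boundary tag for the laser")
  optics <- derive_optics_map(optics)
  D <- tri_optic(mesh, optics, "D")
  mua <- tri_optic(mesh, optics, "mu_a")
  K <- assemble_stiffness(mesh, D)
  M <- assemble_mass(mesh, mua)
  A_sys <- K + M
  rhs <- numeric(nrow(mesh$nodes))
  src <- as_tri_coeff(mesh, source)
  if (any(src != 0)) rhs <- rhs + as.numeric(assemble_mass(mesh, src) %*%
                                             rep(1, nrow(mesh$nodes)))
  # per-edge Fresnel A from the adjacent region's refractive index
  edge_A <- function(tags) {
    e <- mesh$edges[mesh$edges$tag %in% tags, , drop = FALSE]
    nvals <- vapply(optics, `[[`, numeric(1), "A")
    nvals[mesh$cell_region[e$tri]]
  }
  Af <- edge_A("top")
  rb_top <- assemble_robin(mesh, "top", alpha = 1 / (2 * Af),
                           beta = function(r, z) surface_irradiance(beam, r))
  # scale the load by (2/A) per edge: assemble with beta = P0 then correct;
  # simpler: fold (2/A) into beta via a closure over interpolated A. The A
  # coefficient is constant per region and the top edges of one region share
  # it, so assemble per distinct A value.
  A_sys <- A_sys + rb_top$mat
  rhs_top <- numeric(nrow(mesh$nodes))
  for (Aval in unique(Af)) {
    sel_edges <- which(mesh$edges$tag == "top")[Af == Aval]
    sub <- mesh
    sub$edges <- mesh$edges[sel_edges, , drop = FALSE]
    rb <- assemble_robin(sub, "top", alpha = 0,
                         beta = function(r, z) (2 / Aval) * surface_irradiance(beam, r))
    rhs_top <- rhs_top + rb$rhs
  }
  rhs <- rhs + rhs_top
  if (lateral_bc == "robin") {
    for (tg in c("right", "bottom")) {
      Ae <- edge_A(tg)
      if (length(Ae)) {
        rb <- assemble_robin(mesh, tg, alpha = 1 / (2 * Ae), beta = 0)
        A_sys <- A_sys + rb$mat
      }
    }
  }
  phi <- fem_solve(A_sys, rhs)
  scalar_field(mesh, phi, "fluence_W_per_m2")
}
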