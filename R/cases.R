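# Case builders: turn a validated configuration into meshes, property maps
# and run controls, plus the shipped validation presets.

#' Build a simulation case from a configuration
#'
#' @param cfg A `ptt_config` from [load_config()] (or a path to one).
#' @param mesh_scale Multiplies the configured mesh resolution (2 doubles
#'   `nr` and `nz`).
#' @return A `ptt_case`: mesh with regions, raw and derived optics maps,
#'   thermal property map, boundary conditions, beam and run controls.
#' @export
build_case <- function(cfg, mesh_scale = 1) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "ptt_config"))
  nr <- max(1L, round(cfg$mesh$nr * mesh_scale))
  nz <- max(1L, round(cfg$mesh$nz * mesh_scale))
  mesh <- build_rect_mesh(cfg$domain$r_max, cfg$domain$z_max, nr, nz)
  mesh <- assign_regions(mesh, cfg$regions, default = cfg$default_region)
  optics_raw <- cfg$optics[intersect(names(cfg$optics),
                                     unique(c(mesh$cell_region,
                                              names(cfg$optics))))]
  probes <- NULL
  if (!is.null(cfg$run$probes)) {
    pts <- Filter(function(p) !is.null(p$r) && !is.null(p$z), cfg$run$probes)
    if (length(pts))
      probes <- data.frame(r = vapply(pts, `[[`, numeric(1), "r"),
                           z = vapply(pts, `[[`, numeric(1), "z"))
  }
  n_surf <- cfg$optics[[region_at(
    assign_regions(mesh, cfg$regions, cfg$default_region), 0,
    cfg$domain$z_max)]]$n
  structure(list(
    name = cfg$name %||% "case",
    config = cfg,
    mesh = mesh,
    optics = derive_optics_map(cfg$optics),
    optics_raw = cfg$optics,
    thermal = cfg$thermal,
    thermal_bc = cfg$boundary$thermal,
    optical_lateral_bc = cfg$boundary$optical$lateral %||% "robin",
    beam = cfg$beam,
    model = cfg$model %||% "deltap1",
    dt = cfg$run$dt %||% 1,
    duration = cfg$run$duration %||% 0,
    t0 = cfg$run$t0 %||% 37,
    seed = cfg$run$seed %||% 1L,
    photons = cfg$run$photons %||% 1e5,
    probes = probes,
    base_region = cfg$concentration$base_region,
    loaded_region = cfg$concentration$loaded_region,
    n_surface = n_surf
  ), class = "ptt_case")
}

# rebuild the case mesh at a different structured resolution
case_mesh <- function(case, size) {
  mesh <- build_rect_mesh(case$mesh$r_max, case$mesh$z_max, size[1], size[2])
  assign_regions(mesh, case$config$regions, default = case$config$default_region)
}

#' @exportS3Method base::print
print.ptt_case <- function(x, ...) {
  cat("simulation case '", x$name, "'\n", sep = "")
  print(x$mesh)
  print(x$beam)
  cat("  model:", x$model, "| dt =", x$dt, "s, duration =", x$duration, "s\n")
  invisible(x)
}

#' Flat-beam heterogeneous tissue benchmark preset
#'
#' A 20 mm diameter, 5 mm deep nanorod-loaded tumor inside a 40 mm x 10 mm
#' healthy-tissue cylinder under a flat beam; absorption-dominated optics,
#' body-temperature Dirichlet sides, convective top. See the package
#' vignette for the provenance of the numbers.
#'
#' @param mesh_scale Mesh resolution multiplier.
#' @return A `ptt_case`.
#' @export
ptt_case1 <- function(mesh_scale = 1) {
  build_case(system.file("extdata", "case1.yaml", package = "phototherm",
                         mustWork = TRUE), mesh_scale)
}

#' Gaussian-beam deep-inclusion gel phantom preset
#'
#' Agar gel cylinder (radius 15 mm, depth 30 mm) with an embedded
#' nanoparticle-loaded cylinder (radius 5 mm, top face 3 mm deep), Gaussian
#' beam FWHM 7 mm / 1.1 W, convective top surface (5 W K^-1 m^-2), 706 s at
#' dt = 2 s, no metabolic or perfusion terms.
#'
#' @param mesh_scale Mesh resolution multiplier.
#' @return A `ptt_case`.
#' @export
ptt_case2 <- function(mesh_scale = 1) {
  build_case(system.file("extdata", "case2.yaml", package = "phototherm",
                         mustWork = TRUE), mesh_scale)
}

#' Semi-infinite delta-P1 validation setup
#'
#' Homogeneous medium with mu_s'/mu_a = 100 (mu_a = 10 m^-1, mu_s' = 1000
#' m^-1, g = 0.9, n = 1.4) irradiated by a Gaussian beam whose 1/e^2 waist is
#' `r0_factor` transport mean free paths l* = 1/mu_tr. The finite FEM box is
#' sized relative to l* and the waist so boundary truncation stays away from
#' the on-axis comparison range.
#'
#' @param r0_factor Waist in units of l* (the validation sweep uses 1, 10,
#'   100).
#' @param depth_lstar,nz Domain depth in l* units and vertical resolution.
#' @param peak Peak surface irradiance, W m^-2.
#' @return A `ptt_case`-like list with `mesh`, `optics`, `beam` and the
#'   medium's `derived_optics` under `$medium`.
#' @export
ptt_carp_case <- function(r0_factor, depth_lstar = 30, nz = 240,
                          peak = 1e4) {
  props <- optical_properties(mu_a = 10, mu_s = 1e4, g = 0.9, n = 1.4)
  der <- derive_optics(props)
  lstar <- 1 / der$mu_tr
  r0 <- r0_factor * lstar
  r_max <- max(30, 3 * r0_factor) * lstar
  z_max <- depth_lstar * lstar
  nr <- 240L
  mesh <- build_rect_mesh(r_max, z_max, nr, nz)
  mesh <- assign_regions(mesh, list(), default = "medium")
  beam <- beam_gaussian(peak = peak, waist = r0)
  list(mesh = mesh, optics = list(medium = der),
       optics_raw = list(medium = props), beam = beam, medium = der,
       lstar = lstar, r0 = r0)
}
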