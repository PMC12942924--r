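# R-side driver for the compiled voxel Monte Carlo photon-transport oracle.

#' Run the voxel Monte Carlo reference simulation
#'
#' Steady-state photon transport through the axisymmetric medium described by
#' the mesh's region specs: photons are launched from the beam profile at the
#' top surface (normal incidence), propagate in 3D with exponential free
#' paths, implicit-capture weighting, Henyey-Greenstein scattering and
#' Russian roulette, undergo Fresnel reflection at the air interface, and are
#' absorbed at the lateral/bottom faces. Fluence is scored on annular (r, z)
#' voxels with the track-length estimator and normalized to the source power,
#' so results are W m^-2 at steady state. A fixed seed gives bit-reproducible
#' output.
#'
#' @param mesh A `ptt_mesh` (defines the domain box and regions).
#' @param optics Named per-region list of [optical_properties()] (raw, not
#'   derived: the MC uses mu_a, mu_s, g, n directly).
#' @param beam Beam profile.
#' @param photons Number of photons (>= 1).
#' @param seed Integer seed for the internal generator.
#' @param voxel Voxel edge length in meters (applied to both r and z;
#'   rounded so the grid tiles the domain exactly).
#' @param nbatch Number of independent batches kept separate for
#'   standard-error estimation.
#' @param roulette_threshold,roulette_survive Russian-roulette weight
#'   threshold and survival probability.
#' @param specular Transmission factor applied to the incident beam at the
#'   surface (default 1, matching the deterministic solvers).
#' @return An `mc_result`: mean fluence grid (`nrv` x `nzv`), per-batch
#'   array, voxel/grid metadata and exact weight bookkeeping.
#' @export
run_mc <- function(mesh, optics, beam, photons = 1e5, seed = 1L,
                   voxel = 2.5e-4, nbatch = 10L,
                   roulette_threshold = 1e-4, roulette_survive = 0.1,
                   specular = 1) {
  stopifnot(photons >= 1, voxel > 0)
  optics <- lapply(optics, function(o) {
    if (inherits(o, "derived_optics"))
      optical_properties(o$mu_a, o$mu_s, o$g, o$n)
    else o
  })
  nrv <- max(1L, round(mesh$r_max / voxel))
  nzv <- max(1L, round(mesh$z_max / voxel))
  dr <- mesh$r_max / nrv
  dz <- mesh$z_max / nzv
  rc <- (seq_len(nrv) - 0.5) * dr
  zc <- (seq_len(nzv) - 0.5) * dz
  lab <- region_at(mesh, rep(rc, times = nzv), rep(zc, each = nrv))
  regs <- sort(unique(lab))
  miss <- setdiff(regs, names(optics))
  if (length(miss))
    stop("missing optical properties for region(s): ", paste(miss, collapse = ", "))
  reg_id <- match(lab, regs) - 1L
  mua <- vapply(optics[regs], `[[`, numeric(1), "mu_a")
  mus <- vapply(optics[regs], `[[`, numeric(1), "mu_s")
  gg  <- vapply(optics[regs], `[[`, numeric(1), "g")
  nn  <- vapply(optics[regs], `[[`, numeric(1), "n")
  bk <- if (beam$kind == "flat") 0L else 1L
  bp <- if (beam$kind == "flat") beam$radius else beam$waist
  res <- mc_run_cpp(nrv, nzv, dr, dz, reg_id, mua, mus, gg, nn,
                    bk, bp, beam$power, as.double(photons),
                    as.integer(nbatch), as.double(seed),
                    roulette_threshold, roulette_survive, specular)
  fl <- res$fluence
  structure(list(
    fluence = apply(fl, c(1, 2), mean),
    batches = fl,
    dr = dr, dz = dz, nrv = nrv, nzv = nzv,
    r_centers = rc, z_centers = zc,
    photons = photons, seed = seed, nbatch = nbatch,
    launched = sum(res$launched), absorbed = sum(res$absorbed),
    escaped = sum(res$escaped), roulette_net = sum(res$roulette_net),
    mesh = mesh
  ), class = "mc_result")
}

#' @exportS3Method base::print
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo fluence: %g photons on %d x %d voxels (%g mm)\n",
              x$photons, x$nrv, x$nzv, x$dr * 1e3))
  cat(sprintf("  weight: launched %.6g = absorbed %.6g + escaped %.6g + roulette %.3g\n",
              x$launched, x$absorbed, x$escaped, x$roulette_net))
  invisible(x)
}

#' Interpolate a Monte Carlo fluence grid to mesh nodes
#'
#' Bilinear interpolation of the (azimuthally averaged) voxel fluence at each
#' mesh node; nodes outside the voxel-center hull (half a voxel at each edge)
#' are clamped to the nearest voxel value.
#'
#' @param mc An `mc_result`.
#' @param mesh Target `ptt_mesh` (must lie inside the MC domain).
#' @param values Optional grid to interpolate instead of the batch mean
#'   (e.g. one batch).
#' @return A `scalar_field` of fluence at the mesh nodes.
#' @export
interpolate_to_mesh <- function(mc, mesh, values = NULL) {
  g <- if (is.null(values)) mc$fluence else values
  r <- mesh$nodes[, 1]; z <- mesh$nodes[, 2]
  if (any(r > mc$nrv * mc$dr + 1e-12) || any(z > mc$nzv * mc$dz + 1e-12))
    warning("mesh nodes outside the MC grid; clamping")
  vals <- bilinear_grid(mc$r_centers, mc$z_centers, g, r, z)
  scalar_field(mesh, vals, "fluence_W_per_m2")
}

# bilinear interpolation on a rectilinear grid of cell-center samples,
# clamped at the boundary (constant extrapolation over the half-cell margin)
bilinear_grid <- function(xc, yc, g, x, y) {
  nx <- length(xc); ny <- length(yc)
  ix <- findInterval(x, xc)
  iy <- findInterval(y, yc)
  ix <- pmin(pmax(ix, 1L), nx - 1L)
  iy <- pmin(pmax(iy, 1L), ny - 1L)
  if (nx == 1L || ny == 1L) return(g[cbind(pmax(ix, 1L), pmax(iy, 1L))])
  tx <- (x - xc[ix]) / (xc[ix + 1L] - xc[ix])
  ty <- (y - yc[iy]) / (yc[iy + 1L] - yc[iy])
  tx <- pmin(pmax(tx, 0), 1)
  ty <- pmin(pmax(ty, 0), 1)
  g[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    g[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    g[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    g[cbind(ix + 1L, iy + 1L)] * tx * ty
}

#' Standard error of a Monte Carlo functional
#'
#' Applies `fn` to each independent batch grid and returns the standard error
#' of the batch means (the 1/sqrt(B) rule on B batch estimates).
#'
#' @param mc An `mc_result`.
#' @param fn Function mapping a fluence grid (nrv x nzv matrix) to a scalar.
#' @return Standard error of the batch-mean estimate.
#' @export
mc_standard_error <- function(mc, fn) {
  vals <- vapply(seq_len(dim(mc$batches)[3]),
                 function(b) fn(mc$batches[, , b]), numeric(1))
  stats::sd(vals) / sqrt(length(vals))
}
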