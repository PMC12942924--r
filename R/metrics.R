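# Quantitative comparison machinery: region-averaged (cylindrical-volume)
# temperature, relative error, r-volume-weighted RMS error, and the
# mesh-convergence and optical-property sweep drivers.

# exact per-triangle integral of a P1 field against the r-weight:
# int_T u r dA = A/12 * sum_i u_i (2 r_i + r_j + r_k)
region_integrals <- function(mesh, values, tri_sel) {
  g <- tri_geometry(mesh)
  r <- g$r[tri_sel, , drop = FALSE]
  A <- g$area[tri_sel]
  t <- mesh$tri[tri_sel, , drop = FALSE]
  u <- matrix(values[t], ncol = 3)
  num <- A / 12 * (u[, 1] * (2 * r[, 1] + r[, 2] + r[, 3]) +
                   u[, 2] * (2 * r[, 2] + r[, 1] + r[, 3]) +
                   u[, 3] * (2 * r[, 3] + r[, 1] + r[, 2]))
  den <- A * g$rbar[tri_sel]
  c(int_u = sum(num), int_1 = sum(den))
}

#' Region-averaged value of a field (cylindrical volume average)
#'
#' \deqn{T_{av} = \int_{\Omega_R} T\, r\, dV \,/\, \int_{\Omega_R} r\, dV,}
#' the r-weighted mean over the region's triangles, consistent with the
#' cylindrical volume measure. Exact for P1 fields.
#'
#' @param field A `scalar_field` (or a `ptt_mesh` plus `values`).
#' @param region Region label, or `NULL` for the whole domain.
#' @return The average value.
#' @export
average_temperature <- function(field, region = NULL) {
  mesh <- field$mesh
  sel <- if (is.null(region)) rep(TRUE, nrow(mesh$tri))
         else mesh$cell_region == region
  if (!any(sel)) stop("empty region: ", region)
  ints <- region_integrals(mesh, field$values, which(sel))
  unname(ints["int_u"] / ints["int_1"])
}

#' Relative error in percent
#'
#' \eqn{RE = |model - reference| / reference \times 100}, elementwise for
#' vectors/fields or scalar.
#'
#' @param model,reference Scalars, vectors, or `scalar_field`s.
#' @return Relative error(s) in percent.
#' @export
relative_error <- function(model, reference) {
  m <- if (inherits(model, "scalar_field")) model$values else model
  r <- if (inherits(reference, "scalar_field")) reference$values else reference
  if (any(r == 0)) stop("zero reference value in relative error")
  abs(m - r) / abs(r) * 100
}

#' r-volume-weighted RMS difference of two nodal fields
#'
#' \eqn{\sqrt{\int (f - g)^2 r\, dA / \int r\, dA}} over the mesh, computed
#' exactly for P1 fields through the r-weighted mass matrix. Volume weighting
#' keeps the metric comparable across mesh refinements.
#'
#' @param field,reference `scalar_field`s on the same mesh.
#' @return RMS difference in the fields' units.
#' @export
rms_error <- function(field, reference) {
  if (!identical(field$mesh$nodes, reference$mesh$nodes))
    stop("fields live on different meshes")
  e <- field$values - reference$values
  M <- assemble_mass(field$mesh, 1)
  sqrt(as.numeric(e %*% (M %*% e)) / sum(M))
}

#' Mesh-convergence study of fluence RMS error against a fixed reference
#'
#' Re-solves the requested light models on successively refined meshes of the
#' same case and reports the r-volume-weighted RMS fluence error against a
#' fixed reference: either a Monte Carlo run on a fine voxel grid
#' (interpolated to each mesh) or an analytic `function(r, z)`.
#'
#' @param case A `ptt_case` (see [build_case()]).
#' @param models Character vector of light models to compare.
#' @param mesh_sizes List of `c(nr, nz)` pairs, coarse to fine.
#' @param reference `"mc"` or a `function(r, z)`.
#' @param photons,seed,voxel MC reference controls.
#' @return A `comparison_report` data frame: one row per (model, mesh size)
#'   with columns `model`, `nr`, `nz`, `elements`, `rms`, and (for MC
#'   references) `rms_se`, the batch standard error of the RMS metric.
#' @export
convergence_study <- function(case, models = c("deltap1", "sda"),
                              mesh_sizes, reference = "mc",
                              photons = 1e5, seed = 1L, voxel = 2.5e-4) {
  mc <- NULL
  if (identical(reference, "mc")) {
    mesh0 <- case_mesh(case, mesh_sizes[[length(mesh_sizes)]])
    mc <- run_mc(mesh0, case$optics_raw, case$beam, photons = photons,
                 seed = seed, voxel = voxel)
  }
  rows <- list()
  for (ms in mesh_sizes) {
    mesh <- case_mesh(case, ms)
    if (is.null(mc)) {
      ref <- scalar_field(mesh, reference(mesh$nodes[, 1], mesh$nodes[, 2]))
    } else {
      ref <- interpolate_to_mesh(mc, mesh)
    }
    for (mod in models) {
      sol <- solve_fluence(mesh, case$optics, case$beam, model = mod)
      rms <- rms_error(sol$phi, ref)
      se <- NA_real_
      if (!is.null(mc)) {
        se <- mc_standard_error(mc, function(gb) {
          rb <- interpolate_to_mesh(mc, mesh, values = gb)
          rms_error(sol$phi, rb)
        })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = mod, nr = ms[1], nz = ms[2], elements = 2 * ms[1] * ms[2],
        rms = rms, rms_se = se)
    }
  }
  rep_ <- do.call(rbind, rows)
  class(rep_) <- c("comparison_report", "data.frame")
  attr(rep_, "axis") <- "mesh size"
  attr(rep_, "reference") <- if (is.null(mc)) "analytical" else "MC"
  rep_
}

#' Sweep optical conditions and compare models against the MC reference
#'
#' Two sweep axes mirror the package's validation studies:
#' * `axis = "ratio"`: homogeneous absorption-to-scattering sweep at fixed
#'   total extinction; reports each model's relative fluence error (percent,
#'   r-volume-weighted relative RMS) against MC.
#' * `axis = "concentration"`: nanoparticle-loading sweep on a two-region
#'   case; the loaded region's properties interpolate linearly between the
#'   base medium (0 %) and the reference loading (100 %). Each model's
#'   fluence (and MC's) drives an identical bioheat run and the
#'   region-averaged temperatures at the end time are compared.
#'
#' @param case A `ptt_case`.
#' @param axis `"ratio"` or `"concentration"`.
#' @param values Sweep values: mu_a/mu_s ratios, or relative concentrations
#'   in percent.
#' @param models Light models to include.
#' @param photons,seed,voxel,nbatch MC controls (seed is advanced per sweep
#'   value).
#' @param extinction,g Total extinction (m^-1) and anisotropy for the ratio
#'   sweep.
#' @param loaded_region Region whose properties scale with concentration.
#' @return A `comparison_report` data frame.
#' @export
sweep_models <- function(case, axis = c("ratio", "concentration"), values,
                         models = c("deltap1", "sda", "bl"),
                         photons = 1e5, seed = 1L, voxel = 2.5e-4,
                         nbatch = 10L, extinction = 1000, g = 0.5,
                         loaded_region = NULL) {
  axis <- match.arg(axis)
  mesh <- case$mesh
  rows <- list()
  if (axis == "ratio") {
    for (iv in seq_along(values)) {
      rat <- values[iv]
      mu_a <- extinction * rat / (1 + rat)
      mu_s <- extinction / (1 + rat)
      props <- optical_properties(mu_a, mu_s, g = g, n = case$n_surface)
      optics <- stats::setNames(rep(list(props), length(unique(mesh$cell_region))),
                                unique(mesh$cell_region))
      mc <- run_mc(mesh, optics, case$beam, photons = photons,
                   seed = (seed * 1000 + iv) %% 2147483647,
                   voxel = voxel, nbatch = nbatch)
      ref <- interpolate_to_mesh(mc, mesh)
      scale <- sqrt(as.numeric(ref$values %*% (assemble_mass(mesh, 1) %*%
                                               ref$values)) /
                    sum(assemble_mass(mesh, 1)))
      for (mod in models) {
        sol <- solve_fluence(mesh, optics, case$beam, model = mod)
        err <- rms_error(sol$phi, ref) / scale * 100
        se <- mc_standard_error(mc, function(gb) {
          rb <- interpolate_to_mesh(mc, mesh, values = gb)
          rms_error(sol$phi, rb) / scale * 100
        })
        rows[[length(rows) + 1L]] <- data.frame(
          axis = "ratio", value = rat, model = mod, region = "domain",
          error = err, error_se = se)
      }
    }
  } else {
    if (is.null(loaded_region)) loaded_region <- case$loaded_region
    base <- case$optics_raw[[case$base_region]]
    loaded <- case$optics_raw[[loaded_region]]
    op <- bioheat_operator(mesh, case$thermal, case$thermal_bc, case$dt)
    regions <- unique(mesh$cell_region)
    nstep <- ceiling(case$duration / case$dt - 1e-9)
    # the backward-Euler map is affine in the source load, so the
    # batch-to-batch spread of the final region averages is obtained from a
    # one-off adjoint sensitivity per region instead of re-running the
    # transient for every MC batch
    sens <- lapply(regions, function(rg) {
      a <- region_nodal_weights(mesh, rg)
      list(w = bioheat_adjoint_weights(op, nstep, a$weights), norm = a$norm)
    })
    names(sens) <- regions
    for (iv in seq_along(values)) {
      cr <- values[iv]
      optics <- case$optics_raw
      optics[[loaded_region]] <- scale_with_concentration(base, loaded, cr)
      mc <- run_mc(mesh, optics, case$beam, photons = photons,
                   seed = (seed * 1000 + iv) %% 2147483647,
                   voxel = voxel, nbatch = nbatch)
      phi_mc <- interpolate_to_mesh(mc, mesh)
      run_ref <- run_bioheat(mesh, case$thermal, case$thermal_bc,
                             dt = case$dt, t_end = case$duration,
                             T0 = case$t0, optics = optics, phi = phi_mc,
                             operator = op)
      tav_ref <- vapply(regions, function(rg)
        average_temperature(run_ref$final, rg), numeric(1))
      M_mua <- assemble_mass(mesh, tri_optic(mesh, optics, "mu_a"))
      tav_batch <- vapply(seq_len(dim(mc$batches)[3]), function(b) {
        phib <- interpolate_to_mesh(mc, mesh, values = mc$batches[, , b])
        Fb <- as.numeric(M_mua %*% phib$values)
        vapply(regions, function(rg)
          sum(sens[[rg]]$w * Fb) / sens[[rg]]$norm, numeric(1))
      }, numeric(length(regions)))
      if (is.null(dim(tav_batch))) tav_batch <- matrix(tav_batch, nrow = 1)
      se_ref <- apply(tav_batch, 1, stats::sd) / sqrt(ncol(tav_batch))
      names(se_ref) <- regions
      for (mod in models) {
        sol <- solve_fluence(mesh, optics, case$beam, model = mod)
        run_m <- run_bioheat(mesh, case$thermal, case$thermal_bc,
                             dt = case$dt, t_end = case$duration,
                             T0 = case$t0, optics = optics, phi = sol$phi,
                             operator = op)
        for (rg in regions) {
          tav <- average_temperature(run_m$final, rg)
          rows[[length(rows) + 1L]] <- data.frame(
            axis = "concentration", value = cr, model = mod, region = rg,
            tav_model = tav, tav_ref = tav_ref[[rg]],
            dT = tav - tav_ref[[rg]],
            error = relative_error(tav, tav_ref[[rg]]),
            error_se = se_ref[[rg]] / abs(tav_ref[[rg]]) * 100,
            dT_se = se_ref[[rg]])
        }
      }
    }
  }
  rep_ <- do.call(rbind, rows)
  class(rep_) <- c("comparison_report", "data.frame")
  attr(rep_, "axis") <- axis
  attr(rep_, "reference") <- "MC"
  rep_
}

# nodal weights a such that the region volume average of a P1 field T is
# sum(a * T) / norm, with norm = int_region r dV
region_nodal_weights <- function(mesh, region) {
  sel <- which(mesh$cell_region == region)
  if (!length(sel)) stop("empty region: ", region)
  g <- tri_geometry(mesh)
  r <- g$r[sel, , drop = FALSE]; A <- g$area[sel]
  t <- mesh$tri[sel, , drop = FALSE]
  a <- numeric(nrow(mesh$nodes))
  wl <- cbind(A / 12 * (2 * r[, 1] + r[, 2] + r[, 3]),
              A / 12 * (2 * r[, 2] + r[, 1] + r[, 3]),
              A / 12 * (2 * r[, 3] + r[, 1] + r[, 2]))
  for (k in 1:3) {
    add <- tapply(wl[, k], t[, k], sum)
    ii <- as.integer(names(add))
    a[ii] <- a[ii] + add
  }
  list(weights = a, norm = sum(A * g$rbar[sel]))
}

# adjoint of the backward-Euler source-to-final map: returns w with
# a' T_final = (source-independent part) + w' F_src for a constant load F_src
bioheat_adjoint_weights <- function(op, nsteps, a) {
  mask <- rep(TRUE, length(a))
  if (length(op$dir_idx)) mask[op$dir_idx] <- FALSE
  v <- as.numeric(Matrix::solve(op$fact, ifelse(mask, a, 0)))
  w <- v
  if (nsteps > 1L) for (k in seq_len(nsteps - 1L)) {
    rhs <- as.numeric(op$M_cap %*% v)
    rhs[!mask] <- 0
    v <- as.numeric(Matrix::solve(op$fact, rhs))
    w <- w + v
  }
  op$dt * w
}

#' @exportS3Method base::print
print.comparison_report <- function(x, ...) {
  cat("comparison report (axis:", attr(x, "axis"),
      "| reference:", attr(x, "reference"), ")\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
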