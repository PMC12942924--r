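# Transient Pennes bioheat solver: rho Cp dT/dt = div(k grad T) + Qm
# + Wb Cb (Ta - T) + mu_a phi, discretized with r-weighted P1 elements and
# backward-Euler time stepping. The perfusion sink is treated implicitly
# (inside the matrix) and the perfusion/metabolic supplies explicitly on the
# right-hand side, so the scheme is unconditionally stable.

#' Thermal properties of a tissue region
#'
#' @param rho Density, kg m^-3.
#' @param cp Specific heat, J kg^-1 K^-1.
#' @param k Thermal conductivity, W m^-1 K^-1.
#' @param qm Metabolic heat, W m^-3 (default 0).
#' @param wb Blood perfusion rate, kg m^-3 s^-1 (default 0).
#' @param cb Blood specific heat, J kg^-1 K^-1 (default 0).
#' @param ta Arterial blood temperature, degrees C (default 37).
#' @return A `thermal_properties` object.
#' @export
thermal_properties <- function(rho, cp, k, qm = 0, wb = 0, cb = 0, ta = 37) {
  if (rho < 0 || cp < 0 || k < 0 || wb * cb < 0)
    stop("thermal properties must be non-negative")
  structure(list(rho = rho, cp = cp, k = k, qm = qm, wb = wb, cb = cb, ta = ta),
            class = "thermal_properties")
}

tri_thermal <- function(mesh, thermal, what) {
  miss <- setdiff(unique(mesh$cell_region), names(thermal))
  if (length(miss))
    stop("missing thermal properties for region(s): ", paste(miss, collapse = ", "))
  vapply(thermal, function(p) {
    if (is.function(what)) what(p) else p[[what]]
  }, numeric(1))[mesh$cell_region]
}

#' Volumetric heat source from the absorbed fluence
#'
#' The nanoparticle/chromophore heating term mu_a * phi in W m^-3. mu_a is
#' region-resolved; at region-interface nodes the (r-weighted) area average
#' of the adjacent triangles' mu_a is used, consistent with element-wise
#' assembly of the weak source term.
#'
#' @param mesh A `ptt_mesh`.
#' @param optics Named per-region list of optical properties.
#' @param phi Fluence `scalar_field` (W m^-2).
#' @return A `scalar_field` with the source density (W m^-3).
#' @export
heat_source <- function(mesh, optics, phi) {
  stopifnot(inherits(phi, "scalar_field"))
  mua_tri <- tri_optic(mesh, optics, "mu_a")
  g <- tri_geometry(mesh)
  w <- g$area * g$rbar
  num <- den <- numeric(nrow(mesh$nodes))
  for (k in 1:3) {
    add_n <- tapply(w * mua_tri, mesh$tri[, k], sum)
    add_d <- tapply(w, mesh$tri[, k], sum)
    ii <- as.integer(names(add_n))
    num[ii] <- num[ii] + add_n
    den[ii] <- den[ii] + add_d
  }
  scalar_field(mesh, (num / den) * phi$values, "heat_source_W_per_m3")
}

#' Build the backward-Euler bioheat stepping operator
#'
#' Assembles and factorizes the time-stepping system
#' \deqn{(M_{\rho C_p} + \Delta t (K_k + R_h + M_{W_bC_b}))\,T^{j+1} =
#'   M_{\rho C_p} T^j + \Delta t (F_{src} + F_{Q_m} + F_{W_bC_bT_a} +
#'   F_{hT_{ref}}),}
#' so repeated steps (and repeated runs with different sources) reuse one
#' sparse factorization.
#'
#' @param mesh A `ptt_mesh`.
#' @param thermal Named per-region list of [thermal_properties()].
#' @param bc Named list of boundary conditions per facet tag. Each entry is
#'   `list(type = "convection", h = ..., tref = ...)`,
#'   `list(type = "dirichlet", value = ...)` or `list(type = "insulated")`.
#'   Untagged facets (and the axis) are natural/insulated.
#' @param dt Time step, seconds (> 0).
#' @return A `bioheat_operator` used by [run_bioheat()].
#' @export
bioheat_operator <- function(mesh, thermal, bc = list(), dt) {
  stopifnot(dt > 0)
  rho_cp <- tri_thermal(mesh, thermal, function(p) p$rho * p$cp)
  kk     <- tri_thermal(mesh, thermal, "k")
  wbcb   <- tri_thermal(mesh, thermal, function(p) p$wb * p$cb)
  qm     <- tri_thermal(mesh, thermal, "qm")
  wbcbta <- tri_thermal(mesh, thermal, function(p) p$wb * p$cb * p$ta)
  nn <- nrow(mesh$nodes)
  M_cap <- assemble_mass(mesh, rho_cp)
  A <- M_cap + dt * assemble_stiffness(mesh, kk) +
       dt * assemble_mass(mesh, wbcb)
  F_const <- numeric(nn)
  ones <- rep(1, nn)
  if (any(qm != 0)) F_const <- F_const + as.numeric(assemble_mass(mesh, qm) %*% ones)
  if (any(wbcbta != 0))
    F_const <- F_const + as.numeric(assemble_mass(mesh, wbcbta) %*% ones)
  dir_idx <- integer(0); dir_val <- numeric(0)
  for (tag in names(bc)) {
    b <- bc[[tag]]
    if (is.null(b$type)) stop("boundary condition for '", tag, "' lacks a type")
    if (b$type == "convection") {
      rb <- assemble_robin(mesh, tag, alpha = b$h, beta = b$h * b$tref)
      A <- A + dt * rb$mat
      F_const <- F_const + rb$rhs
    } else if (b$type == "dirichlet") {
      e <- mesh$edges[mesh$edges$tag == tag, , drop = FALSE]
      if (!nrow(e)) stop("unknown facet tag: ", tag)
      ii <- unique(c(e$n1, e$n2))
      dir_idx <- c(dir_idx, ii); dir_val <- c(dir_val, rep(b$value, length(ii)))
    } else if (b$type != "insulated") {
      stop("unknown boundary condition type: ", b$type)
    }
  }
  if (length(dir_idx)) {
    keep <- !duplicated(dir_idx)
    dir_idx <- dir_idx[keep]; dir_val <- dir_val[keep]
  }
  A_bc <- A
  if (length(dir_idx)) {
    A_bc[dir_idx, ] <- 0
    A_bc[, dir_idx] <- 0   # symmetric elimination; rhs corrected per step
    d <- Matrix::diag(A_bc); d[dir_idx] <- 1; Matrix::diag(A_bc) <- d
  }
  fact <- tryCatch(Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A_bc),
                                                "CsparseMatrix"), LDL = FALSE),
                   error = function(e)
                     stop("singular bioheat system (all-insulated with zero ",
                          "capacity?): ", conditionMessage(e)))
  structure(list(mesh = mesh, dt = dt, A = A, A_bc = A_bc, fact = fact,
                 M_cap = M_cap, F_const = F_const,
                 dir_idx = dir_idx, dir_val = dir_val),
            class = "bioheat_operator")
}

#' Advance the bioheat solution by one backward-Euler step
#'
#' @param op A [bioheat_operator()].
#' @param T_old Nodal temperature vector at the current time.
#' @param F_src Nodal load vector of the optical source (the weak projection
#'   \eqn{\int \mu_a \phi \, v \, r \, dA}), or 0.
#' @return Nodal temperature vector at the next time level.
#' @export
bioheat_step <- function(op, T_old, F_src = 0) {
  b <- as.numeric(op$M_cap %*% T_old) + op$dt * (op$F_const + F_src)
  if (length(op$dir_idx)) {
    # symmetric elimination: move the known-column contributions to the rhs
    b <- b - as.numeric(op$A[, op$dir_idx, drop = FALSE] %*% op$dir_val)
    b[op$dir_idx] <- op$dir_val
  }
  as.numeric(Matrix::solve(op$fact, b))
}

#' Run a transient bioheat simulation
#'
#' Backward-Euler integration of the Pennes equation driven by a precomputed
#' steady fluence field (the optical problem reaches steady state on a much
#' faster time scale than the thermal one).
#'
#' @param mesh A `ptt_mesh`.
#' @param thermal Named per-region list of [thermal_properties()].
#' @param bc Boundary-condition list (see [bioheat_operator()]).
#' @param dt Time step, s.
#' @param t_end End time, s (final step truncated if not a multiple of dt).
#' @param T0 Initial temperature: scalar or nodal vector, degrees C.
#' @param optics,phi Optical properties and fluence field generating the
#'   source mu_a * phi (either both given or neither).
#' @param source Alternative: a precomputed volumetric source
#'   `scalar_field`/nodal vector (W m^-3).
#' @param probes Optional `data.frame(r, z)` (meters) of probe points whose
#'   temperature traces are recorded every step.
#' @param operator Optional prebuilt [bioheat_operator()] to reuse.
#' @param store `"final"` (default) or `"all"` (keep every snapshot).
#' @return A `bioheat_run`: final field, probe traces (`duration/dt + 1`
#'   rows including t = 0), times, and run metadata.
#' @export
run_bioheat <- function(mesh, thermal, bc = list(), dt, t_end, T0,
                        optics = NULL, phi = NULL, source = NULL,
                        probes = NULL, operator = NULL,
                        store = c("final", "all")) {
  store <- match.arg(store)
  nn <- nrow(mesh$nodes)
  Tn <- if (length(T0) == 1L) rep(T0, nn) else as.numeric(T0)
  stopifnot(length(Tn) == nn)
  if (!is.null(probes)) {
    # errors early if a probe lies outside the domain
    invisible(field_at(mesh, Tn, probes$r, probes$z))
  }
  F_src <- 0
  if (!is.null(optics) && !is.null(phi)) {
    mua_tri <- tri_optic(mesh, optics, "mu_a")
    F_src <- as.numeric(assemble_mass(mesh, mua_tri) %*% phi$values)
  } else if (!is.null(source)) {
    sv <- if (inherits(source, "scalar_field")) source$values else source
    if (length(sv) == 1L) sv <- rep(sv, nn)
    F_src <- as.numeric(assemble_mass(mesh, 1) %*% sv)
  }
  nstep <- if (t_end <= 0) 0L else ceiling(t_end / dt - 1e-9)
  times <- c(0, pmin(seq_len(nstep) * dt, t_end))
  if (is.null(operator) && nstep > 0)
    operator <- bioheat_operator(mesh, thermal, bc, dt)
  snaps <- if (store == "all") vector("list", nstep + 1L) else NULL
  if (store == "all") snaps[[1L]] <- Tn
  ptrace <- if (!is.null(probes))
    matrix(NA_real_, nrow = nstep + 1L, ncol = nrow(probes)) else NULL
  if (!is.null(ptrace)) ptrace[1L, ] <- field_at(mesh, Tn, probes$r, probes$z)
  op <- operator
  for (s in seq_len(nstep)) {
    dts <- times[s + 1L] - times[s]
    if (abs(dts - dt) > 1e-9 * dt) {  # truncated last step
      op_last <- bioheat_operator(mesh, thermal, bc, dts)
      Tn <- bioheat_step(op_last, Tn, F_src)
    } else {
      Tn <- bioheat_step(op, Tn, F_src)
    }
    if (store == "all") snaps[[s + 1L]] <- Tn
    if (!is.null(ptrace)) ptrace[s + 1L, ] <- field_at(mesh, Tn, probes$r, probes$z)
  }
  structure(list(
    final = scalar_field(mesh, Tn, "temperature_C"),
    times = times, probes = probes, probe_trace = ptrace,
    snapshots = snaps, dt = dt, t_end = t_end
  ), class = "bioheat_run")
}

#' @exportS3Method base::print
print.bioheat_run <- function(x, ...) {
  cat(sprintf("bioheat run: %d steps (dt = %g s) to t = %g s; final T in [%.3f, %.3f] C\n",
              length(x$times) - 1L, x$dt, max(x$times),
              min(x$final$values), max(x$final$values)))
  invisible(x)
}

#' @export
plot.bioheat_run <- function(x, which = c("probes", "final"), ...) {
  which <- match.arg(which)
  if (which == "probes" && !is.null(x$probe_trace)) {
    matplot(x$times, x$probe_trace, type = "l", lty = 1,
            xlab = "time [s]", ylab = "temperature [C]", ...)
  } else {
    plot(x$final, ...)
  }
  invisible(x)
}
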