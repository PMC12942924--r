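# Axisymmetric (r-weighted) P1 finite-element assembly and solvers.
#
# All volume and surface integrals carry the cylindrical weight r, as the
# variational forms are written in cylindrical coordinates; the axis r = 0 is
# then a natural (symmetry) boundary by construction. For P1 basis functions
# all integrands are polynomials (degree <= 3 in the barycentric coordinates)
# and the assembly rules below are exact.

# resolve a coefficient given as scalar, per-region named vector/list, or
# per-triangle vector, into a per-triangle numeric vector
as_tri_coeff <- function(mesh, coeff) {
  ntri <- nrow(mesh$tri)
  if (is.list(coeff)) coeff <- unlist(coeff)
  if (length(coeff) == 1L && is.null(names(coeff))) return(rep(as.numeric(coeff), ntri))
  if (!is.null(names(coeff))) {
    miss <- setdiff(unique(mesh$cell_region), names(coeff))
    if (length(miss))
      stop("coefficient missing for region(s): ", paste(miss, collapse = ", "))
    return(as.numeric(coeff[mesh$cell_region]))
  }
  if (length(coeff) == ntri) return(as.numeric(coeff))
  stop("coefficient must be scalar, per-region named, or per-triangle")
}

tri_geometry <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  r <- matrix(p[t, 1], ncol = 3); z <- matrix(p[t, 2], ncol = 3)
  area <- 0.5 * ((r[, 2] - r[, 1]) * (z[, 3] - z[, 1]) -
                 (r[, 3] - r[, 1]) * (z[, 2] - z[, 1]))
  if (any(area <= 0)) stop("degenerate or inverted triangle in mesh")
  list(r = r, z = z, area = area, rbar = rowMeans(r))
}

#' Assemble the r-weighted stiffness matrix
#'
#' Entries \eqn{\int_\Omega c \, \nabla u \cdot \nabla v \; r \, dA} with a
#' per-region (or per-triangle) coefficient `c`. Exact for P1 elements: the
#' basis gradients are constant per triangle and \eqn{\int r \, dA} equals
#' area times centroid radius.
#'
#' @param mesh A `ptt_mesh`.
#' @param coeff Scalar, per-region named vector, or per-triangle vector (>= 0).
#' @return Sparse symmetric positive semidefinite matrix (nodes x nodes).
#' @export
assemble_stiffness <- function(mesh, coeff = 1) {
  cf <- as_tri_coeff(mesh, coeff)
  if (any(cf < 0)) stop("stiffness coefficient must be non-negative")
  g <- tri_geometry(mesh)
  r <- g$r; z <- g$z; A <- g$area
  # P1 gradients: grad(lambda_i) = (b_i, c_i)
  b <- cbind(z[, 2] - z[, 3], z[, 3] - z[, 1], z[, 1] - z[, 2]) / (2 * A)
  c_ <- cbind(r[, 3] - r[, 2], r[, 1] - r[, 3], r[, 2] - r[, 1]) / (2 * A)
  w <- cf * A * g$rbar
  t <- mesh$tri
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (bb in 1:3) {
    k <- k + 1L
    ii[[k]] <- t[, a]; jj[[k]] <- t[, bb]
    xx[[k]] <- w * (b[, a] * b[, bb] + c_[, a] * c_[, bb])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2L))
}

#' Assemble the r-weighted mass matrix
#'
#' Entries \eqn{\int_\Omega c \, u v \; r \, dA}; used for reaction terms
#' (\eqn{\mu_a \phi}), heat capacity (\eqn{\rho C_p T}) and source
#' projections. Exact cubic quadrature in the barycentric coordinates.
#'
#' @inheritParams assemble_stiffness
#' @return Sparse symmetric positive semidefinite matrix.
#' @export
assemble_mass <- function(mesh, coeff = 1) {
  cf <- as_tri_coeff(mesh, coeff)
  g <- tri_geometry(mesh)
  r <- g$r; A <- g$area
  t <- mesh$tri
  w <- cf * A
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  oth <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  for (a in 1:3) for (bb in 1:3) {
    k <- k + 1L
    ii[[k]] <- t[, a]; jj[[k]] <- t[, bb]
    if (a == bb) {
      o <- oth[[a]]
      # int lambda_a^2 r dA = A (r_a/10 + (r_j + r_k)/30)
      xx[[k]] <- w * (r[, a] / 10 + (r[, o[1]] + r[, o[2]]) / 30)
    } else {
      cc <- setdiff(1:3, c(a, bb))
      # int lambda_a lambda_b r dA = A ((r_a + r_b)/30 + r_c/60)
      xx[[k]] <- w * ((r[, a] + r[, bb]) / 30 + r[, cc] / 60)
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2L))
}

#' Assemble r-weighted Robin boundary terms on tagged facets
#'
#' Adds \eqn{\alpha \int u v \, r \, ds} to the system matrix and
#' \eqn{\int \beta v \, r \, ds} to the load vector over boundary edges
#' carrying one of the requested tags. Axis facets (r = 0) contribute nothing:
#' the r-weight vanishes there, which is exactly the natural symmetry
#' condition.
#'
#' @param mesh A `ptt_mesh`.
#' @param tags Character vector of facet tags (`"top"`, `"right"`,
#'   `"bottom"`, `"axis"`).
#' @param alpha Robin coefficient: scalar or one value per selected edge.
#' @param beta Boundary data: scalar, `function(r, z)`, or a nodal vector
#'   (length = number of mesh nodes) evaluated at edge endpoints.
#' @return `list(mat, rhs)`: sparse matrix contribution and load vector.
#' @export
assemble_robin <- function(mesh, tags, alpha = 0, beta = 0) {
  unknown <- setdiff(tags, unique(mesh$edges$tag))
  if (length(unknown))
    stop("unknown facet tag(s): ", paste(unknown, collapse = ", "))
  e <- mesh$edges[mesh$edges$tag %in% tags, , drop = FALSE]
  nn <- nrow(mesh$nodes)
  p <- mesh$nodes
  ra <- p[e$n1, 1]; za <- p[e$n1, 2]
  rb <- p[e$n2, 1]; zb <- p[e$n2, 2]
  L <- sqrt((rb - ra)^2 + (zb - za)^2)
  if (length(alpha) == 1L) alpha <- rep(alpha, nrow(e))
  if (length(alpha) != nrow(e)) stop("alpha must be scalar or per-edge")
  # edge mass with linear r-weight (exact)
  Eaa <- L * (ra / 4 + rb / 12); Ebb <- L * (ra / 12 + rb / 4)
  Eab <- L * (ra + rb) / 12
  mat <- Matrix::sparseMatrix(
    i = c(e$n1, e$n2, e$n1, e$n2),
    j = c(e$n1, e$n2, e$n2, e$n1),
    x = c(alpha * Eaa, alpha * Ebb, alpha * Eab, alpha * Eab),
    dims = c(nn, nn))
  if (is.function(beta)) {
    ba <- beta(ra, za); bb <- beta(rb, zb)
  } else if (length(beta) == nn) {
    ba <- beta[e$n1]; bb <- beta[e$n2]
  } else if (length(beta) == 1L) {
    ba <- rep(beta, nrow(e)); bb <- ba
  } else stop("beta must be scalar, nodal vector, or function(r, z)")
  rhs <- numeric(nn)
  fa <- Eaa * ba + Eab * bb
  fb <- Eab * ba + Ebb * bb
  rhs_add <- tapply(c(fa, fb), c(e$n1, e$n2), sum)
  rhs[as.integer(names(rhs_add))] <- rhs_add
  list(mat = mat, rhs = rhs)
}

#' Apply Dirichlet constraints by symmetric elimination
#'
#' @param A Sparse system matrix.
#' @param b Right-hand side.
#' @param idx Constrained node indices.
#' @param values Prescribed values (recycled).
#' @return `list(A, b)` with rows/columns eliminated and unit diagonal.
#' @export
apply_dirichlet <- function(A, b, idx, values) {
  if (!length(idx)) return(list(A = A, b = b))
  values <- rep_len(values, length(idx))
  b <- b - as.numeric(A[, idx, drop = FALSE] %*% values)
  A[idx, ] <- 0; A[, idx] <- 0
  d <- Matrix::diag(A); d[idx] <- 1; Matrix::diag(A) <- d
  b[idx] <- values
  list(A = A, b = b)
}

#' Solve an assembled linear system
#'
#' Direct sparse factorization by default (used for the elliptic light
#' problems); an optional Jacobi-preconditioned conjugate-gradient path is
#' provided for repeated symmetric positive definite solves.
#'
#' @param A Sparse matrix (after boundary-condition application).
#' @param b Right-hand side.
#' @param method `"direct"` or `"cg"`.
#' @param rel_tol Relative residual tolerance for the iterative path.
#' @param x0 Optional initial iterate for `"cg"`.
#' @return Numeric solution vector; residual norm checked against the
#'   requested tolerance (1e-10 relative for the direct path).
#' @export
fem_solve <- function(A, b, method = c("direct", "cg"), rel_tol = 1e-8,
                      x0 = NULL) {
  method <- match.arg(method)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(numeric(length(b)))
  if (method == "direct") {
    x <- tryCatch(as.numeric(Matrix::solve(A, b)),
                  error = function(e)
                    stop("singular system: is a boundary condition missing? (",
                         conditionMessage(e), ")"))
    res <- sqrt(sum((as.numeric(A %*% x) - b)^2)) / bnorm
    if (!is.finite(res) || res > 1e-10)
      stop(sprintf("direct solve residual %.3g exceeds 1e-10 (singular system?)",
                   res))
    return(x)
  }
  # Jacobi-preconditioned CG
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("CG requires positive diagonal (SPD system)")
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - as.numeric(A %*% x)
  zv <- r / d
  p <- zv
  rz <- sum(r * zv)
  for (it in seq_len(10L * length(b))) {
    Ap <- as.numeric(A %*% p)
    al <- rz / sum(p * Ap)
    x <- x + al * p
    r <- r - al * Ap
    if (sqrt(sum(r^2)) <= rel_tol * bnorm) break
    zv <- r / d
    rz_new <- sum(r * zv)
    p <- zv + (rz_new / rz) * p
    rz <- rz_new
  }
  res <- sqrt(sum((as.numeric(A %*% x) - b)^2)) / bnorm
  if (res > 10 * rel_tol)
    stop(sprintf("CG failed to converge (relative residual %.3g)", res))
  x
}

#' Construct a nodal scalar field on a mesh
#'
#' @param mesh A `ptt_mesh`.
#' @param values One value per node (finite).
#' @param label Quantity label, e.g. `"fluence_W_per_m2"` or
#'   `"temperature_C"`.
#' @return A `scalar_field` object.
#' @export
scalar_field <- function(mesh, values, label = "field") {
  if (length(values) != nrow(mesh$nodes))
    stop("value count must equal node count")
  if (!all(is.finite(values))) stop("scalar field values must be finite")
  structure(list(mesh = mesh, values = as.numeric(values), label = label),
            class = "scalar_field")
}

#' @exportS3Method base::print
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar field '%s' on %d nodes: range [%.6g, %.6g]\n",
              x$label, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.scalar_field <- function(x, nlevels = 12, ...) {
  m <- x$mesh
  g <- node_grid(m, x$values)
  rv <- seq(0, m$r_max, length.out = m$nr + 1L)
  zv <- seq(0, m$z_max, length.out = m$nz + 1L)
  image(rv, zv, g, xlab = "r [m]", ylab = "z [m]",
        col = hcl.colors(64, "inferno"), main = x$label, ...)
  contour(rv, zv, g, nlevels = nlevels, add = TRUE, col = "white", lwd = 0.5)
  invisible(x)
}

#' Evaluate a scalar field at probe points
#' @param field A `scalar_field`.
#' @param r,z Probe coordinates in meters.
#' @return Interpolated values (P1-exact on the mesh).
#' @export
probe_field <- function(field, r, z) {
  field_at(field$mesh, field$values, r, z)
}
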