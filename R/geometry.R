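# Structured axisymmetric triangular meshes of nested cylindrical regions.
#
# The computational domain is the (r, z) half-plane rectangle [0, r_max] x
# [0, z_max]; z = z_max is the irradiated (top) surface, r = 0 the symmetry
# axis. All lengths are SI meters.

#' Declare a cylindrical sub-region of the domain
#'
#' A region is an axis-aligned rectangle in the (r, z) plane, i.e. an annular
#' or solid cylinder after revolution about the axis. Regions may nest; when
#' several regions contain a point, the innermost (smallest-area) one wins.
#'
#' @param label Region name (character scalar).
#' @param r_extent Numeric `c(r_lo, r_hi)` in meters, `0 <= r_lo < r_hi`.
#' @param z_extent Numeric `c(z_lo, z_hi)` in meters, `z_lo < z_hi`.
#' @return An object of class `ptt_region`.
#' @examples
#' region_spec("tumor", c(0, 0.01), c(0.005, 0.01))
#' @export
region_spec <- function(label, r_extent, z_extent) {
  stopifnot(is.character(label), length(label) == 1L,
            length(r_extent) == 2L, length(z_extent) == 2L)
  r_extent <- as.numeric(r_extent); z_extent <- as.numeric(z_extent)
  if (r_extent[1] < 0 || r_extent[2] <= r_extent[1] || z_extent[2] <= z_extent[1])
    stop("invalid region extents for '", label, "'")
  structure(list(label = label, r_extent = r_extent, z_extent = z_extent),
            class = "ptt_region")
}

#' Build a structured axisymmetric triangle mesh on a rectangle
#'
#' Generates a regular `nr` x `nz` grid of quadrilaterals on
#' `[0, r_max] x [0, z_max]` and splits each along one diagonal, yielding
#' `2 * nr * nz` positively oriented P1 triangles and `(nr+1)*(nz+1)` nodes.
#' Boundary edges are tagged `axis` (r = 0), `right` (r = r_max), `bottom`
#' (z = 0) and `top` (z = z_max, the irradiated surface).
#'
#' @param r_max,z_max Domain extents in meters (positive).
#' @param nr,nz Cell counts in r and z (at least 1).
#' @return A `ptt_mesh` object: node coordinates, triangle connectivity,
#'   per-triangle region labels (all `"domain"` until [assign_regions()] is
#'   called), tagged boundary edges, and grid metadata.
#' @examples
#' m <- build_rect_mesh(0.02, 0.01, 40, 20)
#' sum(triangle_areas(m))  # = 0.02 * 0.01
#' @export
build_rect_mesh <- function(r_max, z_max, nr, nz) {
  if (!(r_max > 0) || !(z_max > 0) || nr < 1 || nz < 1)
    stop("invalid geometry: r_max, z_max must be positive and nr, nz >= 1")
  nr <- as.integer(nr); nz <- as.integer(nz)
  rv <- seq(0, r_max, length.out = nr + 1L)
  zv <- seq(0, z_max, length.out = nz + 1L)
  nodes <- cbind(r = rep(rv, times = nz + 1L), z = rep(zv, each = nr + 1L))
  idx <- function(i, j) (j - 1L) * (nr + 1L) + i

  i <- rep(seq_len(nr), times = nz)
  j <- rep(seq_len(nz), each = nr)
  n00 <- idx(i, j); n10 <- idx(i + 1L, j)
  n01 <- idx(i, j + 1L); n11 <- idx(i + 1L, j + 1L)
  # two triangles per quad, diagonal n00--n11, CCW orientation
  tri <- matrix(0L, nrow = 2L * nr * nz, ncol = 3L)
  tri[seq(1L, by = 2L, length.out = nr * nz), ] <- cbind(n00, n10, n11)
  tri[seq(2L, by = 2L, length.out = nr * nz), ] <- cbind(n00, n11, n01)

  cell_tri <- function(ci, cj, which) 2L * ((cj - 1L) * nr + ci - 1L) + which
  jb <- seq_len(nz)
  edges <- rbind(
    data.frame(n1 = idx(seq_len(nr), 1L), n2 = idx(seq_len(nr) + 1L, 1L),
               tag = "bottom", tri = cell_tri(seq_len(nr), 1L, 1L)),
    data.frame(n1 = idx(seq_len(nr), nz + 1L), n2 = idx(seq_len(nr) + 1L, nz + 1L),
               tag = "top", tri = cell_tri(seq_len(nr), nz, 2L)),
    data.frame(n1 = idx(1L, jb), n2 = idx(1L, jb + 1L),
               tag = "axis", tri = cell_tri(1L, jb, 2L)),
    data.frame(n1 = idx(nr + 1L, jb), n2 = idx(nr + 1L, jb + 1L),
               tag = "right", tri = cell_tri(nr, jb, 1L))
  )
  edges$tag <- as.character(edges$tag)

  structure(list(
    nodes = nodes, tri = tri, cell_region = rep("domain", nrow(tri)),
    edges = edges, nr = nr, nz = nz, r_max = r_max, z_max = z_max,
    regions = list(), default_region = "domain"
  ), class = "ptt_mesh")
}

#' Signed areas of all mesh triangles
#' @param mesh A `ptt_mesh`.
#' @return Numeric vector of triangle areas (all positive).
#' @export
triangle_areas <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  r1 <- p[t[, 1], 1]; z1 <- p[t[, 1], 2]
  r2 <- p[t[, 2], 1]; z2 <- p[t[, 2], 2]
  r3 <- p[t[, 3], 1]; z3 <- p[t[, 3], 2]
  0.5 * ((r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1))
}

#' Triangle centroids
#' @param mesh A `ptt_mesh`.
#' @return Two-column matrix of centroid (r, z) coordinates.
#' @export
triangle_centroids <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  cbind((p[t[, 1], 1] + p[t[, 2], 1] + p[t[, 3], 1]) / 3,
        (p[t[, 1], 2] + p[t[, 2], 2] + p[t[, 3], 2]) / 3)
}

#' Label mesh triangles by nested cylindrical regions
#'
#' Each triangle receives the label of the innermost (smallest-area) region
#' whose rectangle contains its centroid, or `default` if none does. When
#' region boundaries coincide with grid lines the labeled area is exact.
#'
#' @param mesh A `ptt_mesh`.
#' @param regions List of [region_spec()] objects (may be empty).
#' @param default Label for triangles outside every region.
#' @return The mesh with `cell_region` filled in and the region specs attached
#'   (used later for point-wise region queries along collimated rays).
#' @export
assign_regions <- function(mesh, regions = list(), default = "tissue") {
  stopifnot(inherits(mesh, "ptt_mesh"))
  if (inherits(regions, "ptt_region")) regions <- list(regions)
  for (rg in regions) {
    if (!inherits(rg, "ptt_region")) stop("regions must be region_spec objects")
    if (rg$r_extent[2] > mesh$r_max + 1e-12 || rg$z_extent[2] > mesh$z_max + 1e-12)
      stop("region '", rg$label, "' extends outside the domain box")
  }
  cen <- triangle_centroids(mesh)
  lab <- rep(default, nrow(mesh$tri))
  if (length(regions)) {
    areas <- vapply(regions, function(g)
      diff(g$r_extent) * diff(g$z_extent), numeric(1))
    for (k in order(areas, decreasing = TRUE)) {  # innermost applied last
      g <- regions[[k]]
      inside <- cen[, 1] >= g$r_extent[1] & cen[, 1] <= g$r_extent[2] &
                cen[, 2] >= g$z_extent[1] & cen[, 2] <= g$z_extent[2]
      lab[inside] <- g$label
    }
  }
  mesh$cell_region <- lab
  mesh$regions <- regions
  mesh$default_region <- default
  mesh
}

#' Region label at arbitrary points
#'
#' Applies the same innermost-region-wins rule as [assign_regions()] to
#' arbitrary (r, z) points (boundary-inclusive), falling back to the mesh's
#' default label.
#'
#' @param mesh A `ptt_mesh` with regions attached.
#' @param r,z Point coordinates (vectors, recycled).
#' @return Character vector of region labels.
#' @export
region_at <- function(mesh, r, z) {
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  lab <- rep(mesh$default_region, n)
  regions <- mesh$regions
  if (length(regions)) {
    areas <- vapply(regions, function(g)
      diff(g$r_extent) * diff(g$z_extent), numeric(1))
    for (k in order(areas, decreasing = TRUE)) {
      g <- regions[[k]]
      inside <- r >= g$r_extent[1] & r <= g$r_extent[2] &
                z >= g$z_extent[1] & z <= g$z_extent[2]
      lab[inside] <- g$label
    }
  }
  lab
}

#' @exportS3Method base::print
print.ptt_mesh <- function(x, ...) {
  cat("Axisymmetric triangle mesh:", nrow(x$nodes), "nodes,",
      nrow(x$tri), "triangles (", x$nr, "x", x$nz, "cells )\n")
  cat("  domain: r in [0,", format(x$r_max), "] m, z in [0,",
      format(x$z_max), "] m\n")
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$cell_region)),
                                  table(x$cell_region)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ptt_mesh <- function(x, col_by_region = TRUE, ...) {
  cen <- triangle_centroids(x)
  regs <- factor(x$cell_region)
  plot(NA, xlim = c(0, x$r_max), ylim = c(0, x$z_max),
       xlab = "r [m]", ylab = "z [m]", asp = 1, ...)
  p <- x$nodes; t <- x$tri
  for (k in 1:3) {
    k2 <- if (k == 3) 1L else k + 1L
    segments(p[t[, k], 1], p[t[, k], 2], p[t[, k2], 1], p[t[, k2], 2],
             col = "grey70")
  }
  if (col_by_region && nlevels(regs) > 1)
    points(cen[, 1], cen[, 2], pch = 20, cex = 0.3, col = as.integer(regs))
  invisible(x)
}

# nodes arranged on the structured grid as an (nr+1) x (nz+1) matrix
node_grid <- function(mesh, values) {
  matrix(values, nrow = mesh$nr + 1L, ncol = mesh$nz + 1L)
}

# locate values of a nodal field at arbitrary points by P1 interpolation
# (exploits the structured grid: cell lookup is O(1))
field_at <- function(mesh, values, r, z) {
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  if (any(r < -1e-12 | r > mesh$r_max + 1e-12 |
          z < -1e-12 | z > mesh$z_max + 1e-12))
    stop("probe point outside the domain")
  dr <- mesh$r_max / mesh$nr; dz <- mesh$z_max / mesh$nz
  ci <- pmin(pmax(floor(r / dr), 0), mesh$nr - 1)
  cj <- pmin(pmax(floor(z / dz), 0), mesh$nz - 1)
  # local coordinates in the cell
  xr <- r / dr - ci; xz <- z / dz - cj
  idx <- function(i, j) (j) * (mesh$nr + 1L) + i + 1L  # 0-based i,j
  v00 <- values[idx(ci, cj)]; v10 <- values[idx(ci + 1, cj)]
  v01 <- values[idx(ci, cj + 1)]; v11 <- values[idx(ci + 1, cj + 1)]
  # diagonal n00--n11 splits the cell; P1 interpolation on each triangle
  lower <- xz <= xr  # triangle (n00, n10, n11)
  out <- numeric(n)
  out[lower] <- (v00 * (1 - xr) + v10 * (xr - xz) + v11 * xz)[lower]
  out[!lower] <- (v00 * (1 - xz) + v11 * xr + v01 * (xz - xr))[!lower]
  out
}
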