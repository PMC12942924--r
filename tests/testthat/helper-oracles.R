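# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code; no stored data.

# small homogeneous test mesh
toy_mesh <- function(r_max = 1, z_max = 1, nr = 8, nz = 8, label = "medium") {
  assign_regions(build_rect_mesh(r_max, z_max, nr, nz), list(), label)
}

# layered closed-form attenuation of a normally incident ray:
# product of exp(-mu_l * path_l) over the layers traversed down to `depth`
layered_attenuation <- function(depth, breaks, mus) {
  # breaks: depths of layer interfaces from the surface (increasing),
  # mus[l]: coefficient of the layer between breaks[l-1] and breaks[l]
  lo <- c(0, breaks)
  hi <- c(breaks, Inf)
  vapply(depth, function(d) {
    path <- pmax(0, pmin(d, hi) - lo)
    exp(-sum(path * mus))
  }, numeric(1))
}

# independent Fresnel-moment oracle for the boundary parameter A:
# numerical integration of the internal reflection moments over a normal
# slab, A = (1 + R2) / (1 - R1)
fresnel_A_oracle <- function(n) {
  RF <- function(mu) {
    vapply(mu, function(ci) {
      si <- sqrt(max(0, 1 - ci^2)); st <- n * si
      if (st >= 1) return(1)
      ct <- sqrt(1 - st^2)
      rs <- (n * ci - ct) / (n * ci + ct)
      rp <- (n * ct - ci) / (n * ct + ci)
      0.5 * (rs^2 + rp^2)
    }, numeric(1))
  }
  R1 <- stats::integrate(function(m) 2 * m * RF(m), 0, 1, rel.tol = 1e-10)$value
  R2 <- stats::integrate(function(m) 3 * m^2 * RF(m), 0, 1, rel.tol = 1e-10)$value
  (1 + R2) / (1 - R1)
}

# exact voxel-averaged Beer-Lambert depth profile for the pure-absorber MC
# check (compares like with like: the MC scores voxel averages)
beer_lambert_voxel_avg <- function(p0, mu, z_lo, z_hi) {
  p0 * (exp(-mu * z_lo) - exp(-mu * z_hi)) / (mu * (z_hi - z_lo))
}
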