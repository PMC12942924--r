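test_that("beam profiles satisfy their defining widths and normalization", {
  bg <- beam_gaussian(power = 1.1, fwhm = 7e-3)
  w <- 7e-3 / sqrt(2 * log(2))
  expect_equal(bg$waist, w)
  # 1/e^2 at the waist radius
  expect_equal(surface_irradiance(bg, w), bg$peak * exp(-2))
  # half the peak at FWHM/2
  expect_equal(surface_irradiance(bg, 3.5e-3), bg$peak / 2)
  # total power recovered by quadrature
  pw <- stats::integrate(function(r) surface_irradiance(bg, r) * 2 * pi * r,
                         0, Inf, rel.tol = 1e-10)$value
  expect_equal(pw, 1.1, tolerance = 1e-8)
  bf <- beam_flat(5e3, 0.01)
  expect_equal(surface_irradiance(bf, c(0.005, 0.02)), c(5e3, 0))
  expect_equal(bf$power, 5e3 * pi * 1e-4)
  expect_error(beam_gaussian(power = 1, peak = 1, fwhm = 1e-3), "exactly one")
})

test_that("collimated transport matches the layered closed form to 1e-6", {
  mesh <- assign_regions(
    build_rect_mesh(0.02, 0.01, 10, 25),
    list(region_spec("upper", c(0, 0.02), c(0.006, 0.01))), "lower")
  opt <- list(upper = optical_properties(100, 50, 0.8),
              lower = optical_properties(300, 10, 0.5))
  du <- derive_optics(opt$upper); dl <- derive_optics(opt$lower)
  pc <- solve_collimated(mesh, opt, beam_flat(1000, 0.02))
  onax <- which(mesh$nodes[, 1] == 0)
  depth <- 0.01 - mesh$nodes[onax, 2]
  exact <- 1000 * layered_attenuation(depth, 0.004,
                                      c(du$mu_t_star, dl$mu_t_star))
  expect_equal(pc$values[onax], exact, tolerance = 1e-6)
  # homogeneous single-layer sanity: e^{-1} at depth 1/mu
  mh <- toy_mesh(0.01, 0.01, 2, 40)
  oh <- list(medium = optical_properties(60, 50, 0.5))
  mt <- derive_optics(oh$medium)$mu_t_star
  ph <- solve_collimated(mh, oh, beam_flat(1, 0.01))
  expect_equal(ph$values[1], exp(-mt * 0.01), tolerance = 1e-6)
})

test_that("a transparent medium transmits the surface irradiance unchanged", {
  m <- toy_mesh(0.01, 0.01, 4, 4)
  opt <- list(medium = optical_properties(0, 1e-300, 0))  # mu_t* ~ 0
  pc <- solve_collimated(m, opt, beam_flat(123, 0.01))
  expect_equal(pc$values, rep(123, nrow(m$nodes)), tolerance = 1e-12)
})

test_that("Beer-Lambert attenuates with the total extinction", {
  m <- toy_mesh(0.01, 0.01, 2, 50)
  opt <- list(medium = optical_properties(100, 400, 0.9))
  bl <- solve_collimated(m, opt, beam_flat(1, 0.01), model = "bl")
  expect_equal(bl$values[1], exp(-500 * 0.01), tolerance = 1e-6)
  # delta-P1 collimated decays with mu_t* < mu_t instead
  pc <- solve_collimated(m, opt, beam_flat(1, 0.01))
  expect_gt(pc$values[1], bl$values[1])
})

test_that("zero collimated input gives zero diffuse fluence", {
  m <- toy_mesh(0.02, 0.02, 10, 10)
  opt <- list(medium = optical_properties(10, 1000, 0.9))
  pc <- scalar_field(m, numeric(nrow(m$nodes)))
  pd <- solve_diffuse(m, opt, pc)
  expect_equal(pd$values, numeric(nrow(m$nodes)))
})

test_that("delta-P1 collapses to Beer-Lambert as scattering vanishes", {
  m <- toy_mesh(0.02, 0.02, 20, 40)
  beam <- beam_flat(1e3, 0.02)
  opt <- list(medium = optical_properties(200, 1e-4, 0))
  sol <- solve_fluence(m, opt, beam, model = "deltap1")
  bl <- solve_fluence(m, opt, beam, model = "bl")
  expect_lt(max(abs(sol$phi$values - bl$phi$values)) / max(bl$phi$values), 1e-5)
})

test_that("on-axis delta-P1 fluence matches the semi-infinite analytical solution", {
  # mu_s'/mu_a = 100 medium, Gaussian waist 10 l*: the FEM solution on a
  # finite box reproduces the Hankel-transform analytical solution in the
  # interior (coarser grid than the validation preset to keep this quick)
  cs <- ptt_carp_case(10, nz = 120)
  sol <- solve_fluence(cs$mesh, cs$optics, cs$beam, model = "deltap1")
  zpl <- seq(1, 12, by = 1) * cs$lstar
  fem <- probe_field(sol$phi, 0, cs$mesh$z_max - zpl)
  ana <- deltap1_semi_infinite(cs$medium, cs$r0, cs$beam$peak, zpl)
  expect_lt(max(abs(fem / ana$phi - 1)), 0.10)
})

test_that("total fluence is the nodewise sum and checks meshes", {
  m <- toy_mesh()
  a <- scalar_field(m, runif(nrow(m$nodes)))
  b <- scalar_field(m, runif(nrow(m$nodes)))
  expect_equal(total_fluence(a, b)$values, a$values + b$values)
  m2 <- toy_mesh(nr = 9)
  expect_error(total_fluence(a, scalar_field(m2, numeric(nrow(m2$nodes)))),
               "different meshes")
})

test_that("both delta-P1 components are linear in beam power", {
  m <- toy_mesh(0.02, 0.02, 12, 12)
  opt <- list(medium = optical_properties(50, 500, 0.8))
  s1 <- solve_fluence(m, opt, beam_flat(1e3, 0.01), model = "deltap1")
  s2 <- solve_fluence(m, opt, beam_flat(3e3, 0.01), model = "deltap1")
  expect_equal(s2$phi$values, 3 * s1$phi$values, tolerance = 1e-10)
})

test_that("oblique beams are rejected", {
  m <- toy_mesh()
  beam <- beam_flat(1, 0.5)
  beam$direction <- c(1, 0)
  expect_error(solve_collimated(m, list(medium = optical_properties(1, 1, 0)),
                                beam), "normal incidence")
})
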