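test_that("weight bookkeeping is exact and seeded runs are reproducible", {
  mesh <- toy_mesh(0.01, 0.01, 10, 10)
  opt <- list(medium = optical_properties(50, 500, 0.8, n = 1.37))
  mc <- run_mc(mesh, opt, beam_flat(1000, 0.008), photons = 2e4, seed = 42,
               voxel = 1e-3)
  expect_equal(mc$launched, 2e4)
  expect_equal(mc$launched, mc$absorbed + mc$escaped + mc$roulette_net,
               tolerance = 1e-12)
  mc2 <- run_mc(mesh, opt, beam_flat(1000, 0.008), photons = 2e4, seed = 42,
                voxel = 1e-3)
  expect_identical(mc$fluence, mc2$fluence)
  mc3 <- run_mc(mesh, opt, beam_flat(1000, 0.008), photons = 2e4, seed = 43,
                voxel = 1e-3)
  expect_false(identical(mc$fluence, mc3$fluence))
})

test_that("a pure absorber reproduces the Beer-Lambert depth profile", {
  mesh <- toy_mesh(0.01, 0.01, 10, 10)
  opt <- list(medium = optical_properties(200, 0, 0, n = 1))
  mc <- run_mc(mesh, opt, beam_flat(1000, 0.01), photons = 2e5, seed = 7,
               voxel = 5e-4)
  prof <- colMeans(mc$fluence)
  se <- vapply(seq_along(mc$z_centers), function(j)
    mc_standard_error(mc, function(g) mean(g[, j])), numeric(1))
  z_lo <- 0.01 - (mc$z_centers + mc$dz / 2)
  z_hi <- 0.01 - (mc$z_centers - mc$dz / 2)
  exact <- beer_lambert_voxel_avg(1000, 200, z_lo, z_hi)
  expect_true(all(abs(prof - exact) <= 3 * se + 1e-9 * exact))
})

test_that("similarity relation: g = 0 and g = 0.9 agree deep at equal mu_s'", {
  mesh <- toy_mesh(0.04, 0.04, 8, 8)
  beam <- beam_flat(1000, 0.04)
  ma <- run_mc(mesh, list(medium = optical_properties(10, 1000, 0.9, n = 1)),
               beam, photons = 1e5, seed = 3, voxel = 2e-3)
  mb <- run_mc(mesh, list(medium = optical_properties(10, 100, 0, n = 1)),
               beam, photons = 1e5, seed = 4, voxel = 2e-3)
  band <- which(0.04 - ma$z_centers > 0.015 & 0.04 - ma$z_centers < 0.025)
  fa <- mean(ma$fluence[, band]); fb <- mean(mb$fluence[, band])
  se <- sqrt(mc_standard_error(ma, function(g) mean(g[, band]))^2 +
             mc_standard_error(mb, function(g) mean(g[, band]))^2)
  expect_lt(abs(fa - fb), max(4 * se, 0.03 * fb))
})

test_that("region-mean standard error scales like 1/sqrt(N)", {
  mesh <- toy_mesh(0.02, 0.02, 4, 4)
  opt <- list(medium = optical_properties(100, 300, 0.5, n = 1.33))
  beam <- beam_flat(1000, 0.01)
  ses <- vapply(c(1e3, 1e4, 1e5), function(np) {
    mc <- run_mc(mesh, opt, beam, photons = np, seed = 9, voxel = 2e-3)
    mc_standard_error(mc, mean)
  }, numeric(1))
  ratios <- ses[-3] / ses[-1]
  # each 10x photon increase shrinks the SE ~ sqrt(10) = 3.16
  expect_true(all(ratios > 1.6 & ratios < 6.5))
})

test_that("voxel interpolation reproduces constants and linear-in-z fields", {
  mesh <- toy_mesh(0.01, 0.01, 7, 9)
  opt <- list(medium = optical_properties(10, 10, 0, n = 1))
  mc <- run_mc(mesh, opt, beam_flat(1, 0.01), photons = 1e3, seed = 1,
               voxel = 1e-3)
  cgrid <- matrix(3.14, mc$nrv, mc$nzv)
  ci <- interpolate_to_mesh(mc, mesh, values = cgrid)
  expect_equal(ci$values, rep(3.14, nrow(mesh$nodes)))
  zgrid <- matrix(rep(mc$z_centers, each = mc$nrv), mc$nrv, mc$nzv)
  zi <- interpolate_to_mesh(mc, mesh, values = zgrid)
  interior <- mesh$nodes[, 2] > mc$dz / 2 & mesh$nodes[, 2] < 0.01 - mc$dz / 2
  expect_equal(zi$values[interior], mesh$nodes[interior, 2], tolerance = 1e-12)
})
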