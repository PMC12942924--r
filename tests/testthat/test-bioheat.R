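test_that("uniform temperature at the convection reference is a fixed point", {
  mesh <- toy_mesh(0.02, 0.01, 12, 6, "tissue")
  th <- list(tissue = thermal_properties(1000, 4000, 0.5))
  bc <- list(top = list(type = "convection", h = 10, tref = 30))
  run <- run_bioheat(mesh, th, bc, dt = 5, t_end = 50, T0 = 30)
  expect_equal(run$final$values, rep(30, nrow(mesh$nodes)), tolerance = 1e-12)
})

test_that("insulated constant-source runs heat at q dt / (rho Cp) per step", {
  mesh <- toy_mesh(0.02, 0.01, 10, 5, "tissue")
  rho <- 1000; cp <- 4000; q <- 1e5
  th <- list(tissue = thermal_properties(rho, cp, 0.5))
  run <- run_bioheat(mesh, th, list(), dt = 2, t_end = 20, T0 = 20, source = q)
  expect_equal(average_temperature(run$final) - 20, q * 20 / (rho * cp),
               tolerance = 1e-10)
  # the field stays spatially uniform
  expect_lt(diff(range(run$final$values)), 1e-10)
})

test_that("perfusion relaxes an insulated tissue to arterial temperature", {
  mesh <- toy_mesh(0.02, 0.01, 8, 4, "tissue")
  rho <- 1000; cp <- 4000; wb <- 2; cb <- 3800; ta <- 37
  th <- list(tissue = thermal_properties(rho, cp, 0.5, wb = wb, cb = cb, ta = ta))
  run <- run_bioheat(mesh, th, list(), dt = 1, t_end = 100, T0 = 30,
                     store = "all")
  # discrete solution of the scalar ODE rho Cp T' = Wb Cb (Ta - T) under
  # backward Euler: geometric approach to Ta
  lam <- wb * cb / (rho * cp)
  discrete <- ta + (30 - ta) * (1 / (1 + lam * 1))^100
  expect_equal(mean(run$final$values), discrete, tolerance = 1e-9)
  exact <- ta + (30 - ta) * exp(-lam * 100)
  expect_equal(mean(run$final$values), exact, tolerance = 0.01)
  # monotone approach
  means <- vapply(run$snapshots, mean, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("backward Euler is first-order accurate in dt", {
  mesh <- toy_mesh(0.02, 0.01, 10, 5, "tissue")
  th <- list(tissue = thermal_properties(1000, 4000, 0.5))
  bc <- list(top = list(type = "convection", h = 100, tref = 20))
  sol <- lapply(c(4, 2, 1), function(dt)
    run_bioheat(mesh, th, bc, dt = dt, t_end = 80, T0 = 50)$final$values)
  e_coarse <- max(abs(sol[[1]] - sol[[3]]))
  e_fine <- max(abs(sol[[2]] - sol[[3]]))
  # errors vs the dt = 1 run scale like (dt - 1): ratio ~ 3 for O(dt)
  expect_gt(e_coarse / e_fine, 2)
  expect_lt(e_coarse / e_fine, 4.5)
})

test_that("zero-duration runs return the initial field; probes validate", {
  mesh <- toy_mesh(0.02, 0.01, 6, 3, "tissue")
  th <- list(tissue = thermal_properties(1000, 4000, 0.5))
  run <- run_bioheat(mesh, th, list(), dt = 1, t_end = 0, T0 = 42)
  expect_equal(run$final$values, rep(42, nrow(mesh$nodes)))
  expect_error(
    run_bioheat(mesh, th, list(), dt = 1, t_end = 0, T0 = 42,
                probes = data.frame(r = 0.05, z = 0)),
    "outside the domain")
})

test_that("source-free convection stays within the data bounds (maximum behavior)", {
  mesh <- toy_mesh(0.02, 0.01, 12, 6, "tissue")
  th <- list(tissue = thermal_properties(1000, 4000, 0.5))
  bc <- list(top = list(type = "convection", h = 100, tref = 20))
  run <- run_bioheat(mesh, th, bc, dt = 5, t_end = 200, T0 = 50, store = "all")
  # the consistent-mass P1 scheme admits a tiny transient overshoot near the
  # cooled boundary; it must stay below 0.5 % of the data range and decay
  band <- 0.005 * (50 - 20)
  over <- vapply(run$snapshots, function(s) max(s) - 50, numeric(1))
  for (snap in run$snapshots) {
    expect_gte(min(snap), 20 - band)
    expect_lte(max(snap), 50 + band)
  }
  expect_lt(max(tail(over, 10)), 1e-6)
})

test_that("Dirichlet walls pin the boundary temperature", {
  mesh <- toy_mesh(0.02, 0.01, 10, 5, "tissue")
  th <- list(tissue = thermal_properties(1000, 4000, 0.5))
  bc <- list(right = list(type = "dirichlet", value = 37),
             bottom = list(type = "dirichlet", value = 37))
  run <- run_bioheat(mesh, th, bc, dt = 10, t_end = 100, T0 = 45, source = 1e4)
  wall <- unique(c(mesh$edges$n1[mesh$edges$tag %in% c("right", "bottom")],
                   mesh$edges$n2[mesh$edges$tag %in% c("right", "bottom")]))
  expect_equal(run$final$values[wall], rep(37, length(wall)), tolerance = 1e-10)
  expect_gt(max(run$final$values), 37)
})

test_that("the heat source is mu_a * phi with area-weighted interface values", {
  mesh <- assign_regions(build_rect_mesh(0.02, 0.01, 8, 4),
                         list(region_spec("hot", c(0, 0.01), c(0, 0.01))),
                         "cold")
  opt <- list(hot = optical_properties(31, 0, 0),
              cold = optical_properties(2, 0, 0))
  phi <- scalar_field(mesh, rep(1000, nrow(mesh$nodes)))
  hs <- heat_source(mesh, opt, phi)
  # interior of each region: plain product
  interior_hot <- mesh$nodes[, 1] < 0.009
  expect_equal(hs$values[interior_hot],
               rep(31 * 1000, sum(interior_hot)), tolerance = 1e-12)
  interior_cold <- mesh$nodes[, 1] > 0.011
  expect_equal(hs$values[interior_cold],
               rep(2 * 1000, sum(interior_cold)), tolerance = 1e-12)
  # interface nodes carry the r-weighted area average of adjacent mu_a
  iface <- which(abs(mesh$nodes[, 1] - 0.01) < 1e-12)
  expect_true(all(hs$values[iface] > 2 * 1000 & hs$values[iface] < 31 * 1000))
  # zero fluence -> zero source
  hs0 <- heat_source(mesh, opt, scalar_field(mesh, numeric(nrow(mesh$nodes))))
  expect_equal(hs0$values, numeric(nrow(mesh$nodes)))
})

test_that("steady state is independent of the initial condition", {
  mesh <- toy_mesh(0.02, 0.01, 8, 4, "tissue")
  th <- list(tissue = thermal_properties(1000, 4000, 0.5))
  bc <- list(top = list(type = "convection", h = 50, tref = 25))
  rA <- run_bioheat(mesh, th, bc, dt = 50, t_end = 5e4, T0 = 20, source = 1e4)
  rB <- run_bioheat(mesh, th, bc, dt = 50, t_end = 5e4, T0 = 60, source = 1e4)
  expect_equal(rA$final$values, rB$final$values, tolerance = 1e-6)
})
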