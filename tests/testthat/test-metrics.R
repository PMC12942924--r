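test_that("region averages normalize exactly and add up over regions", {
  mesh <- assign_regions(build_rect_mesh(1, 1, 10, 10),
                         list(region_spec("inner", c(0, 0.5), c(0, 1))),
                         "outer")
  cf <- scalar_field(mesh, rep(7.5, nrow(mesh$nodes)))
  expect_equal(average_temperature(cf), 7.5)
  expect_equal(average_temperature(cf, "inner"), 7.5)
  expect_equal(average_temperature(cf, "outer"), 7.5)
  # T = z on the unit square: int z r / int r = 1/2
  zf <- scalar_field(mesh, mesh$nodes[, 2])
  expect_equal(average_temperature(zf), 0.5, tolerance = 1e-13)
  # additivity: whole-domain average is the r-volume-weighted region mean
  g <- scalar_field(mesh, mesh$nodes[, 1] + 2 * mesh$nodes[, 2])
  vol <- function(rg) {
    sel <- mesh$cell_region == rg
    sum((triangle_areas(mesh) * triangle_centroids(mesh)[, 1])[sel])
  }
  vi <- vol("inner"); vo <- vol("outer")
  combined <- (average_temperature(g, "inner") * vi +
               average_temperature(g, "outer") * vo) / (vi + vo)
  expect_equal(average_temperature(g), combined, tolerance = 1e-12)
  expect_error(average_temperature(cf, "nope"), "empty region")
})

test_that("relative error follows its definition", {
  expect_equal(relative_error(44, 40), 10)
  expect_equal(relative_error(40, 40), 0)
  expect_equal(relative_error(c(30, 50), c(40, 40)), c(25, 25))
  expect_error(relative_error(1, 0), "zero reference")
})

test_that("RMS error behaves as a volume-weighted norm", {
  mesh <- toy_mesh(1, 1, 8, 8)
  a <- scalar_field(mesh, stats::rnorm(nrow(mesh$nodes)))
  expect_equal(rms_error(a, a), 0)
  # uniform offset c gives RMS = |c|
  b <- scalar_field(mesh, a$values + 3)
  expect_equal(rms_error(b, a), 3, tolerance = 1e-12)
  # linear scaling of a perturbation
  p <- stats::rnorm(nrow(mesh$nodes))
  e1 <- rms_error(scalar_field(mesh, a$values + p), a)
  e2 <- rms_error(scalar_field(mesh, a$values + 2 * p), a)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  expect_error(rms_error(a, scalar_field(toy_mesh(nr = 9), numeric(90))),
               "different meshes")
})

test_that("convergence against a manufactured reference is strictly decreasing", {
  case <- ptt_case1(mesh_scale = 0.1)
  ref_fun <- function(r, z) 1e3 * exp(-300 * (case$mesh$z_max - z)) * cos(50 * r)
  rep_ <- convergence_study(case, models = "deltap1",
                            mesh_sizes = list(c(12, 6), c(24, 12), c(48, 24)),
                            reference = ref_fun)
  expect_equal(nrow(rep_), 3)
  # FEM fields differ from the fixed smooth reference by less on finer meshes
  expect_true(all(diff(rep_$rms) < 0))
  # single mesh size: one row, checks vacuous
  one <- convergence_study(case, models = "deltap1",
                           mesh_sizes = list(c(12, 6)), reference = ref_fun)
  expect_equal(nrow(one), 1)
})

test_that("zero-loading concentration sweep reduces to the homogeneous gel", {
  case <- ptt_case2(mesh_scale = 0.27)  # ~20 x 32 cells
  case$dt <- 10; case$duration <- 60
  rep_ <- sweep_models(case, axis = "concentration", values = 0,
                       models = "deltap1", photons = 2e4, seed = 2,
                       voxel = 1e-3)
  # at 0 % the loaded region is plain gel: model-vs-MC temperature
  # differences are small everywhere (sub-0.1 K scale of this short run)
  expect_lt(max(abs(rep_$dT)), 0.05)
  expect_true(all(rep_$error_se > 0))
})

test_that("report writers produce readable CSV/JSON with provenance", {
  df <- data.frame(model = "deltap1", value = 1.5, error = 0.1)
  class(df) <- c("comparison_report", "data.frame")
  attr(df, "axis") <- "test"; attr(df, "reference") <- "none"
  td <- withr::local_tempdir()
  out <- write_report(df, file.path(td, "rep.json"),
                      config = list(a = 1, b = "x"))
  expect_true(all(file.exists(out)))
  back <- jsonlite::read_json(out[1])
  expect_equal(back$rows[[1]]$value, 1.5)
  expect_match(back$config_hash, "^[0-9a-f]{32}$")
  csv <- utils::read.csv(out[2])
  expect_equal(csv$error, 0.1)
})
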