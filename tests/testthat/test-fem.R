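test_that("r-weighted stiffness is exact, symmetric and annihilates constants", {
  m <- toy_mesh(1, 1, 8, 8)
  K <- assemble_stiffness(m, 1)
  expect_equal(max(abs(K - Matrix::t(K))), 0)
  const <- rep(4.2, nrow(m$nodes))
  expect_lt(max(abs(K %*% const)), 1e-12)
  # discrete energy of u = z on the unit square: int |grad u|^2 r dA = 1/2
  u <- m$nodes[, 2]
  expect_equal(as.numeric(u %*% (K %*% u)), 0.5, tolerance = 1e-13)
})

test_that("r-weighted mass totals the cylindrical measure", {
  m <- toy_mesh(1, 1, 5, 9)
  M <- assemble_mass(m, 1)
  expect_equal(sum(M), 0.5, tolerance = 1e-13)       # int_0^1 int_0^1 r dr dz
  expect_equal(max(abs(M - Matrix::t(M))), 0)
  expect_equal(sum(abs(assemble_mass(m, 0))), 0)
  # exactness: total is resolution-independent
  expect_equal(sum(assemble_mass(toy_mesh(1, 1, 17, 3), 1)), 0.5,
               tolerance = 1e-13)
})

test_that("Robin boundary terms integrate the r-weighted edge measure", {
  m <- toy_mesh(1, 1, 6, 6)
  rb <- assemble_robin(m, "top", alpha = 1, beta = 0)
  expect_equal(sum(rb$mat), 0.5, tolerance = 1e-13)  # int_0^1 r dr
  expect_equal(sum(abs(rb$rhs)), 0)
  # alpha = 0, beta = 0 -> no-op
  rb0 <- assemble_robin(m, "right", alpha = 0, beta = 0)
  expect_equal(sum(abs(rb0$mat)), 0)
  # axis facets contribute nothing (r-weight vanishes)
  ra <- assemble_robin(m, "axis", alpha = 1, beta = 1)
  expect_equal(sum(abs(ra$mat)), 0)
  expect_equal(sum(abs(ra$rhs)), 0)
  # linear beta integrates exactly: int_0^1 beta(r) r dr with beta = r
  rbl <- assemble_robin(m, "top", alpha = 0, beta = function(r, z) r)
  expect_equal(sum(rbl$rhs), 1 / 3, tolerance = 1e-13)
  expect_error(assemble_robin(m, "lid", 1, 0), "unknown facet tag")
})

test_that("P1 Galerkin reproduces solutions linear in z exactly", {
  m <- toy_mesh(1, 1, 7, 5)
  A <- assemble_stiffness(m, 1)
  uex <- 2 + 3 * m$nodes[, 2]
  bidx <- unique(c(m$edges$n1, m$edges$n2))
  sys <- apply_dirichlet(A, numeric(nrow(m$nodes)), bidx, uex[bidx])
  sol <- fem_solve(sys$A, sys$b)
  expect_equal(sol, uex, tolerance = 1e-12)
})

test_that("pure-Neumann Laplace is reported singular", {
  m <- toy_mesh(1, 1, 4, 4)
  A <- assemble_stiffness(m, 1)
  b <- numeric(nrow(m$nodes)); b[1] <- 1
  expect_error(fem_solve(A, b), "singular")
})

test_that("manufactured smooth solution converges at second order in L2", {
  # u = z^3 + r^2 z: the cylindrical Laplacian (1/r)(r u_r)_r + u_zz
  # equals 10 z, so the r-weighted weak form with source f = -10 z and
  # Dirichlet data from u has u as its exact solution; u is not in the P1
  # space, so the discrete error decays at the optimal L2 rate
  errs <- vapply(c(8, 16, 32), function(n) {
    m <- toy_mesh(1, 1, n, n)
    A <- assemble_stiffness(m, 1)
    M <- assemble_mass(m, 1)
    rr <- m$nodes[, 1]; zz <- m$nodes[, 2]
    uex <- zz^3 + rr^2 * zz
    b <- as.numeric(M %*% (-10 * zz))
    bidx <- unique(c(m$edges$n1, m$edges$n2))
    sys <- apply_dirichlet(A, b, bidx, uex[bidx])
    sol <- fem_solve(sys$A, sys$b)
    e <- sol - uex
    sqrt(as.numeric(e %*% (M %*% e)))
  }, numeric(1))
  rates <- log2(errs[-3] / errs[-1])
  expect_true(all(rates > 1.8))
})

test_that("the iterative solve path matches the direct one", {
  m <- toy_mesh(1, 1, 10, 10)
  A <- assemble_stiffness(m, 1) + assemble_mass(m, 5)
  b <- as.numeric(assemble_mass(m, 1) %*% (1 + m$nodes[, 1]))
  xd <- fem_solve(A, b)
  xi <- fem_solve(A, b, method = "cg", rel_tol = 1e-10)
  expect_equal(xi, xd, tolerance = 1e-7)
})

test_that("scalar fields validate their inputs", {
  m <- toy_mesh()
  expect_error(scalar_field(m, 1:3), "node count")
  expect_error(scalar_field(m, rep(NaN, nrow(m$nodes))), "finite")
})
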