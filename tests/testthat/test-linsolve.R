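test_that("CG handles identity, zero right-hand side and small FEM systems", {
  n <- 20
  I <- as_sparse_system(diag(n))
  b <- rnorm(n)
  sol <- cg(I, b, solver_options(tolerance = 1e-12))
  expect_equal(sol$x, b, tolerance = 1e-12)
  expect_lte(sol$report$iterations, 2L)

  solz <- cg(I, numeric(n))
  expect_equal(solz$x, numeric(n))
  expect_identical(solz$report$iterations, 0L)
  expect_identical(solz$report$reason, "converged")

  # dense factorisation oracle on a small mesh system
  m <- cyl_mesh(12)
  p <- optical_params(m, mua = 0.01, kappa = 0.3)
  sys <- assemble_forward(m, p, 0)
  set.seed(1)
  b <- rnorm(m$n_nodes)
  xd <- solve(densify(sys$Stilde), b)
  for (pc in c("diagonal", "none")) {
    sol <- cg(sys$Stilde, b, solver_options(tolerance = 1e-12,
                                            preconditioner = pc))
    expect_identical(sol$report$reason, "converged")
    expect_lt(max(abs(sol$x - xd)) / max(abs(xd)), 1e-8)
  }
})

test_that("converged reports satisfy the true-residual contract", {
  m <- cyl_mesh(12)
  p <- optical_params(m, mua = 0.05, mus = 2)
  sys <- assemble_forward(m, p, 0)
  set.seed(2)
  b <- rnorm(m$n_nodes)
  opts <- solver_options(tolerance = 1e-9, preconditioner = "none")
  sol <- cg(sys$Stilde, b, opts)
  expect_identical(sol$report$reason, "converged")
  # recompute the residual wholly outside the solver
  r <- b - sp_matvec(sys$Stilde, sol$x)
  expect_lte(sqrt(sum(r^2)) / sqrt(sum(b^2)), opts$tolerance)
  expect_equal(sol$report$residual, sqrt(sum(r^2)) / sqrt(sum(b^2)),
               tolerance = 1e-6)
})

test_that("BiCGSTAB solves closed-form, dense-oracle and singular cases", {
  # 1x1 complex system (3+4i) x = 5
  S1 <- as_sparse_system(matrix(3 + 4i, 1, 1))
  sol1 <- bicgstab(S1, 5 + 0i, solver_options(tolerance = 1e-14))
  expect_equal(sol1$x, 5 * (3 - 4i) / 25, tolerance = 1e-12)

  # small complex FEM system vs dense LU oracle
  m <- cyl_mesh(12)
  p <- optical_params(m, mua = 0.01, kappa = 0.3)
  om <- omega_from_mhz(100)
  sys <- assemble_forward(m, p, om)
  set.seed(3)
  b <- complex(real = rnorm(m$n_nodes), imaginary = rnorm(m$n_nodes))
  xd <- solve(densify(sys$S), b)
  sol <- bicgstab(sys$S, b, solver_options(tolerance = 1e-12,
                                           max_iterations = 10000))
  expect_identical(sol$report$reason, "converged")
  expect_lt(max(Mod(sol$x - xd)) / max(Mod(xd)), 1e-8)

  # deliberately singular system: breakdown reported, no NaN leak
  Ssing <- as_sparse_system(matrix(c(1, 1, 1, 1), 2, 2))
  sols <- bicgstab(Ssing, c(1, 2),
                   solver_options(tolerance = 1e-12, max_iterations = 50,
                                  preconditioner = "none"))
  expect_true(sols$report$reason %in% c("breakdown", "stagnated",
                                        "max_iterations"))
  expect_true(all(is.finite(sols$x)))
})

test_that("complex expansion reproduces the block structure and the complex solution", {
  # 1x1: (a + bi) -> [[a, -b], [b, a]]
  S <- as_sparse_system(matrix(2 + 3i, 1, 1))
  ex <- complex_expand(S, 1 + 0i)
  expect_equal(densify(ex$S2), rbind(c(2, -3), c(3, 2)),
               ignore_attr = TRUE)

  # omega = 0 (zero imaginary part): block diagonal, two decoupled
  # real solves
  m <- cyl_mesh(12)
  p <- optical_params(m, mua = 0.01, kappa = 0.3)
  sys <- assemble_forward(m, p, omega_from_mhz(100))
  S0 <- sys$S
  S0$values <- complex(real = Re(S0$values), imaginary = 0)
  n <- S0$n
  ex0 <- complex_expand(S0, as.complex(rnorm(n)))
  D <- densify(ex0$S2)
  expect_true(all(D[seq_len(n), n + seq_len(n)] == 0))
  expect_true(all(D[n + seq_len(n), seq_len(n)] == 0))

  # random 20x20 complex system: expanded solve equals dense complex
  # solve to 1e-10
  set.seed(4)
  M <- matrix(complex(real = rnorm(400), imaginary = rnorm(400)), 20) +
    diag(20) * 8
  b <- complex(real = rnorm(20), imaginary = rnorm(20))
  Ssp <- as_sparse_system(M)
  sol <- solve_complex(Ssp, b, solver_options(tolerance = 1e-13,
                                              max_iterations = 2000))
  expect_lt(max(Mod(sol$x - solve(M, b))) / max(Mod(solve(M, b))), 1e-10)
})

test_that("expanded and direct-complex strategies agree within tolerance", {
  m <- cyl_mesh(10)
  p <- optical_params(m, mua = 0.01, kappa = 0.3)
  sys <- assemble_forward(m, p, omega_from_mhz(100))
  Q <- dotfem:::source_vector(m, source_spec(c(25, 0, 0)))
  opts <- solver_options(tolerance = 1e-12, max_iterations = 20000)
  xe <- solve_complex(sys$S, as.complex(Q), opts)
  xd <- solve_complex(sys$S, as.complex(Q), opts, strategy = "direct")
  expect_identical(xe$report$reason, "converged")
  expect_identical(xd$report$reason, "converged")
  expect_lt(max(Mod(xe$x - xd$x)) / max(Mod(xe$x)), 1e-9)
})

test_that("diagonal preconditioner is exact for diagonal systems and reduces iterations", {
  D <- as_sparse_system(diag(c(1, 10, 100, 1000)))
  b <- c(1, 2, 3, 4)
  sol <- cg(D, b, solver_options(tolerance = 1e-12))
  expect_lte(sol$report$iterations, 2L)
  expect_equal(sol$x, b / c(1, 10, 100, 1000), tolerance = 1e-12)

  # applying the preconditioner of the identity is the identity map
  pc <- diagonal_preconditioner(as_sparse_system(diag(3)))
  expect_equal(pc$apply(c(1, 2, 3)), c(1, 2, 3))
  expect_error(diagonal_preconditioner(as_sparse_system(
    matrix(c(0, 1, 1, 0), 2))), "diagonal")

  # on the cylinder fixture the preconditioned iteration needs no more
  # iterations than the unpreconditioned one, both verified against the
  # dense oracle
  m <- cyl_mesh(8)
  p <- optical_params(m, mua = 0.01, kappa = 0.3)
  sys <- assemble_forward(m, p, 0)
  Q <- dotfem:::source_vector(m, source_spec(c(25, 0, 0)))
  o1 <- cg(sys$Stilde, Q, solver_options(tolerance = 1e-10))
  o2 <- cg(sys$Stilde, Q, solver_options(tolerance = 1e-10,
                                         preconditioner = "none"))
  expect_lte(o1$report$iterations, o2$report$iterations)
  xd <- solve(densify(sys$Stilde), Q)
  expect_lt(max(abs(o1$x - xd)) / max(abs(xd)), 1e-7)
  expect_lt(max(abs(o2$x - xd)) / max(abs(xd)), 1e-7)
})

test_that("iterative solutions match dense direct solves across small meshes", {
  # oracle equivalence on meshes up to ~500 nodes at tolerance 1e-12
  for (res in c(12, 8)) {
    m <- cyl_mesh(res)
    expect_lte(m$n_nodes, 500)
    p <- optical_params(m, mua = 0.025, mus = 1.2)
    om <- omega_from_mhz(100)
    sys <- assemble_forward(m, p, om)
    set.seed(res)
    b <- rnorm(m$n_nodes)

    xcg <- cg(sys$Stilde, b, solver_options(tolerance = 1e-12))
    expect_lt(max(abs(xcg$x - solve(densify(sys$Stilde), b))) /
              max(abs(xcg$x)), 1e-8)

    bc <- as.complex(b)
    xe <- solve_complex(sys$S, bc,
                        solver_options(tolerance = 1e-12,
                                       max_iterations = 20000))
    xdense <- solve(densify(sys$S), bc)
    expect_lt(max(Mod(xe$x - xdense)) / max(Mod(xdense)), 1e-8)
  }
})

test_that("single-precision path keeps the matrix and vectors in float", {
  m <- cyl_mesh(10)
  p <- optical_params(m, mua = 0.01, kappa = 0.3)
  sys <- assemble_forward(m, p, 0)
  Q <- dotfem:::source_vector(m, source_spec(c(25, 0, 0)))
  sol <- cg(sys$Stilde, Q, solver_options(tolerance = 1e-6,
                                          max_iterations = 5000,
                                          precision = "single"))
  # solution entries are representable in single precision up to the
  # final diagonal rescaling (applied in double)
  expect_lt(sol$report$residual, 1e-5)
  xd <- cg(sys$Stilde, Q, solver_options(tolerance = 1e-12))$x
  expect_lt(max(abs(sol$x - xd)) / max(abs(xd)), 1e-3)
  # but it is not the double-precision answer
  expect_gt(max(abs(sol$x - xd)), 0)
})
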