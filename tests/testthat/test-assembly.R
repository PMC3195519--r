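test_that("stiffness matrix has the constant null space, linearity and the gradient-product form", {
  m <- cyl_mesh(10)
  K <- assemble_stiffness(m, kappa = 0.3)
  ones <- rep(1, m$n_nodes)
  expect_lt(max(abs(sp_matvec(K, ones))), 1e-12 * max(abs(K$values)))

  # symmetry
  Kd <- densify(K)
  expect_equal(Kd, t(Kd), tolerance = 1e-13)

  # doubling kappa doubles every entry exactly
  K2 <- assemble_stiffness(m, kappa = 0.6)
  expect_equal(K2$values, 2 * K$values)

  # single unit tet vs the direct gradient-product oracle G V G^T
  mu <- unit_tet_mesh()
  K1 <- densify(assemble_stiffness(mu, kappa = 1))
  g <- dotfem:::element_gradients(mu, 1)
  expect_equal(K1, (1 / 6) * (g %*% t(g)), tolerance = 1e-14,
               ignore_attr = TRUE)

  expect_error(assemble_stiffness(m, kappa = -1), "positive")
})

test_that("absorption matrix conserves mass and matches the multinomial diagonal", {
  m <- cyl_mesh(10)
  mua <- 0.01
  C <- assemble_absorption(m, mua)
  ones <- rep(1, m$n_nodes)
  expect_equal(sum(ones * sp_matvec(C, ones)),
               mua * sum(element_volumes(m)), tolerance = 1e-10)

  mu <- unit_tet_mesh()
  C1 <- densify(assemble_absorption(mu, 1))
  V <- 1 / 6
  expect_equal(diag(C1), rep(V * (1 / 20 + 3 / 60), 4))  # = V/10
  expect_equal(C1[1, 2], V * (2 / 60 + 2 / 120))         # = V/20
  expect_true(all(densify(assemble_absorption(mu, 0)) == 0))
})

test_that("boundary matrix lives on boundary nodes and integrates to the surface area", {
  mu <- unit_tet_mesh()
  A1 <- densify(assemble_boundary(mu))
  ones <- rep(1, 4)
  expect_equal(sum(ones * (A1 %*% ones)),
               sum(dotfem:::face_areas(mu)), tolerance = 1e-12)

  m <- cyl_mesh(8)
  A <- assemble_boundary(m)
  ones <- rep(1, m$n_nodes)
  expect_equal(sum(ones * sp_matvec(A, ones)),
               sum(dotfem:::face_areas(m)), tolerance = 1e-10)

  # interior node rows identically zero
  bnodes <- unique(as.vector(m$boundary_faces))
  interior <- setdiff(seq_len(m$n_nodes), bnodes)
  rows <- rep.int(seq_len(A$n), diff(A$row_ptr))
  expect_true(all(A$values[rows %in% interior] == 0))
})

test_that("mass matrix is SPD with the closed-form entries and 1'B1 = V/c", {
  mu <- unit_tet_mesh()
  B1 <- densify(assemble_mass(mu, c = 1))
  V <- 1 / 6
  expect_equal(diag(B1), rep(V / 10, 4))
  expect_equal(B1[1, 2], V / 20)

  m <- cyl_mesh(10)
  cc <- 0.2998 / 1.4
  B <- assemble_mass(m, cc)
  ones <- rep(1, m$n_nodes)
  expect_equal(sum(ones * sp_matvec(B, ones)),
               sum(element_volumes(m)) / cc, tolerance = 1e-10)

  # dense eigensolver oracle on a tiny mesh: strictly positive spectrum
  ms <- cyl_mesh(12)
  ev <- eigen(densify(assemble_mass(ms, cc)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(assemble_mass(m, -1), "positive")
})

test_that("system matrix combines K + C + gamma A + i omega B and is complex symmetric", {
  m <- cyl_mesh(10)
  p <- optical_params(m, mua = 0.01, kappa = 0.3)
  pat <- dotfem:::csr_pattern(m)
  K <- assemble_stiffness(m, p$kappa, pat)
  C <- assemble_absorption(m, p$mua, pat)
  A <- assemble_boundary(m, pat)
  B <- assemble_mass(m, p$c, pat)

  # omega = 0: real, equals Stilde
  S0 <- assemble_system(K, C, A, B, p$gamma, omega = 0)
  expect_false(is.complex(S0$values))
  expect_equal(S0$values, K$values + C$values + p$gamma * A$values)

  om <- omega_from_mhz(100)
  S <- assemble_system(K, C, A, B, p$gamma, om)
  expect_true(is.complex(S$values))
  expect_equal(Im(S$values), om * B$values)
  expect_equal(Re(S$values), S0$values)

  Sd <- densify(S)
  expect_lt(max(Mod(Sd - t(Sd))), 1e-12 * max(Mod(Sd)))

  # Stilde positive definite for positive parameters (dense eigen oracle)
  ms <- cyl_mesh(12)
  ps <- optical_params(ms, mua = 0.01, kappa = 0.3)
  sys <- assemble_forward(ms, ps, 0)
  ev <- eigen(densify(sys$Stilde), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("source assembly integrates boundary profiles exactly", {
  m <- cyl_mesh(8)
  bnodes <- unique(as.vector(m$boundary_faces))
  q <- numeric(m$n_nodes)
  q[bnodes] <- 1
  Q <- assemble_source(m, q)
  expect_equal(sum(Q), sum(dotfem:::face_areas(m)), tolerance = 1e-10)

  # single-node impulse is supported on the node's boundary patch
  q2 <- numeric(m$n_nodes)
  q2[bnodes[1]] <- 1
  Q2 <- assemble_source(m, q2)
  bf <- m$boundary_faces
  patch <- unique(as.vector(bf[rowSums(bf == bnodes[1]) > 0, ]))
  expect_true(all(which(Q2 != 0) %in% patch))

  # Gaussian profile: sum Q equals the face-quadrature of the
  # interpolated profile (computed independently from face areas)
  sigma <- 3
  centre <- c(25, 0, 0)
  qg <- numeric(m$n_nodes)
  qg[bnodes] <- exp(-rowSums((m$nodes[bnodes, , drop = FALSE] -
    matrix(centre, length(bnodes), 3, byrow = TRUE))^2) / (2 * sigma^2))
  Qg <- assemble_source(m, qg)
  S <- dotfem:::face_areas(m)
  quad <- sum(S / 3 * rowSums(matrix(qg[bf], ncol = 3)))
  expect_equal(sum(Qg), quad, tolerance = 1e-8)

  # interior support is an error by default, ignorable on request
  qbad <- q2
  interior <- setdiff(seq_len(m$n_nodes), bnodes)
  qbad[interior[1]] <- 1
  expect_error(assemble_source(m, qbad), "interior")
  expect_warning(Qi <- assemble_source(m, qbad, on_interior = "ignore"),
                 "ignoring")
  expect_equal(Qi, Q2)
})

test_that("precision demotion rounds within half-ulp, is idempotent and flags overflow", {
  m <- cyl_mesh(10)
  K <- assemble_stiffness(m, kappa = 0.3)
  Ks <- demote_precision(K)
  expect_identical(Ks$precision, "single")
  expect_identical(Ks$col_ind, K$col_ind)
  expect_true(all(abs(Ks$values - K$values) <= 2^-24 * abs(K$values)))
  expect_identical(demote_precision(Ks)$values, Ks$values)
  expect_error(to_single(1e39), "overflow")
})

test_that("native single-precision assembly differs from demoted double assembly", {
  # high-valence vertices on the cylinder accumulate many element
  # contributions; summing them in float loses digits that
  # assemble-in-double-then-demote keeps
  m <- cyl_mesh(5)
  p <- optical_params(m, mua = 0.01, kappa = 0.3)
  pat <- dotfem:::csr_pattern(m)
  Kd <- demote_precision(assemble_stiffness(m, p$kappa, pat))
  Kn <- assemble_stiffness(m, p$kappa, pat, precision = "single")
  expect_identical(Kn$precision, "single")
  expect_gt(max(abs(Kn$values - Kd$values)), 0)
})

test_that("assembly is permutation-equivariant and matches a matrix-free oracle", {
  m <- cyl_mesh(12)
  p <- optical_params(m, mua = 0.02, mus = 1)
  K <- assemble_stiffness(m, p$kappa)

  # permutation equivariance
  set.seed(11)
  perm <- sample(m$n_nodes)
  inv <- integer(m$n_nodes); inv[perm] <- seq_len(m$n_nodes)
  mp <- tet_mesh(m$nodes[perm, , drop = FALSE],
                 matrix(inv[m$elements], ncol = 4))
  Kp <- assemble_stiffness(mp, p$kappa[perm])
  expect_equal(densify(Kp), densify(K)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)

  # matrix-free oracle: element-wise accumulation of K v without global
  # assembly
  v <- rnorm(m$n_nodes)
  Kv <- numeric(m$n_nodes)
  kap <- p$kappa
  for (e in seq_len(nrow(m$elements))) {
    idx <- m$elements[e, ]
    li <- local_integrals(m, e)
    Kv[idx] <- Kv[idx] + mean(kap[idx]) * (li$stiffness %*% v[idx])
  }
  expect_equal(sp_matvec(K, v), Kv, tolerance = 1e-12)
})
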