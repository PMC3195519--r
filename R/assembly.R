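#' Optical parameter set
#'
#' Nodal optical coefficients plus the scalar boundary terms used by the
#' diffusion forward model. The diffusion coefficient defaults to
#' \eqn{\kappa = [3(\mu_a + \mu_s)]^{-1}} (mm) from the nodal absorption
#' \eqn{\mu_a} and reduced scattering \eqn{\mu_s} (mm^-1); it may also be
#' supplied directly. The speed of light in the medium is
#' `c = c0 / n_refr` with `c0 = 0.2998` mm/ps. The boundary reflectance
#' term \eqn{\zeta(n)} may be given explicitly; by default it is computed
#' from the refractive index with the Groenhuis polynomial fit for the
#' effective internal reflection coefficient,
#' \eqn{R_{eff} = -1.440 n^{-2} + 0.710 n^{-1} + 0.668 + 0.0636 n},
#' \eqn{\zeta = (1 + R_{eff}) / (1 - R_{eff})}. The exitance scale is
#' \eqn{\gamma = c / (2\zeta)} (mm/ps), exactly.
#'
#' @param mesh a [tet_mesh()] (used for the node count) or an integer
#'   node count.
#' @param mua nodal absorption coefficient, mm^-1 (scalar recycled).
#' @param mus nodal reduced scattering coefficient, mm^-1 (scalar
#'   recycled). May be omitted when `kappa` is given.
#' @param kappa nodal diffusion coefficient, mm; derived from `mua` and
#'   `mus` when `NULL`.
#' @param n_refr refractive index of the medium (scalar).
#' @param zeta boundary reflectance term; computed from `n_refr` when
#'   `NULL`.
#' @param c0 speed of light in vacuum, mm/ps.
#' @return An object of class `optical_params` with fields `mua`,
#'   `kappa`, `n_refr`, `c`, `zeta`, `gamma` and `zeta_source`
#'   (`"given"` or `"fit"`, recorded in run manifests).
#' @export
optical_params <- function(mesh, mua, mus = NULL, kappa = NULL,
                           n_refr = 1.4, zeta = NULL, c0 = 0.2998) {
  n <- if (inherits(mesh, "tet_mesh")) mesh$n_nodes else as.integer(mesh)
  mua <- rep_len(as.numeric(mua), n)
  if (any(mua <= 0)) stop("mua must be positive at every node")
  if (is.null(kappa)) {
    if (is.null(mus)) stop("supply either mus or kappa")
    mus <- rep_len(as.numeric(mus), n)
    if (any(mus <= 0)) stop("mus must be positive at every node")
    kappa <- 1 / (3 * (mua + mus))
  } else {
    kappa <- rep_len(as.numeric(kappa), n)
    if (any(kappa <= 0)) stop("kappa must be positive at every node")
  }
  stopifnot(n_refr >= 1, c0 > 0)
  cc <- c0 / n_refr
  zeta_source <- "given"
  if (is.null(zeta)) {
    reff <- -1.440 / n_refr^2 + 0.710 / n_refr + 0.668 + 0.0636 * n_refr
    zeta <- (1 + reff) / (1 - reff)
    zeta_source <- "fit"
  }
  stopifnot(zeta > 0)
  structure(list(mua = mua, kappa = kappa, n_refr = n_refr, c = cc,
                 zeta = zeta, gamma = cc / (2 * zeta),
                 zeta_source = zeta_source, n_nodes = n),
            class = "optical_params")
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf(paste0("<optical_params: %d nodes, mua %s mm^-1, ",
                     "kappa %s mm, n = %.3g, zeta = %.4g (%s), ",
                     "gamma = %.4g mm/ps>\n"),
              x$n_nodes,
              if (diff(range(x$mua)) == 0) sprintf("%.4g", x$mua[1L])
              else "heterogeneous",
              if (diff(range(x$kappa)) == 0) sprintf("%.4g", x$kappa[1L])
              else "heterogeneous",
              x$n_refr, x$zeta, x$zeta_source, x$gamma))
  invisible(x)
}

# --- sparsity pattern -------------------------------------------------------

# Global CSR pattern of the element connectivity, plus the slot position
# of every element-local (i, j) contribution in element-major order.
# All four FEM matrices are assembled on this one pattern so that their
# linear combination is value-wise.
csr_pattern <- function(mesh) {
  el <- mesh$elements
  n <- mesh$n_nodes
  ii <- rep(1:4, each = 4L)
  jj <- rep.int(1:4, 4L)
  I <- as.vector(t(el[, ii, drop = FALSE]))   # element-major stream
  J <- as.vector(t(el[, jj, drop = FALSE]))
  key <- (as.numeric(I) - 1) * n + (as.numeric(J) - 1)
  uk <- sort(unique(key))
  pos <- findInterval(key, uk)                # exact hits by construction
  row1 <- as.integer(uk %/% n) + 1L
  list(n = n, nnz = length(uk),
       row_ptr = c(0L, cumsum(tabulate(row1, nbins = n))),
       col_ind = as.integer(uk %% n),
       pos = pos, key = uk)
}

# Map a face-local (or any) triplet stream onto slots of an existing
# pattern; errors if an entry is absent from the pattern.
pattern_slots <- function(pattern, i, j) {
  key <- (as.numeric(i) - 1) * pattern$n + (as.numeric(j) - 1)
  pos <- findInterval(key, pattern$key)
  bad <- pos < 1L | pattern$key[pmax(pos, 1L)] != key
  if (any(bad)) stop("entry outside the mesh sparsity pattern")
  pos
}

# Per-element geometry shared by the assembly routines: volumes and the
# 16 gradient dot products V * (grad u_i . grad u_j), element-major.
element_geometry <- function(mesh) {
  nodes <- mesh$nodes
  el <- mesh$elements
  a <- nodes[el[, 1L], , drop = FALSE]
  e1 <- nodes[el[, 2L], , drop = FALSE] - a
  e2 <- nodes[el[, 3L], , drop = FALSE] - a
  e3 <- nodes[el[, 4L], , drop = FALSE] - a
  cross <- function(u, v)
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  c23 <- cross(e2, e3)
  det <- e1[, 1L] * c23[, 1L] + e1[, 2L] * c23[, 2L] + e1[, 3L] * c23[, 3L]
  g1 <- c23 / det
  g2 <- cross(e3, e1) / det
  g3 <- cross(e1, e2) / det
  g0 <- -(g1 + g2 + g3)
  V <- det / 6  # positive by mesh orientation convention
  g <- list(g0, g1, g2, g3)
  gdot <- matrix(0, nrow(el), 16L)
  k <- 1L
  for (i in 1:4) for (j in 1:4) {
    gdot[, k] <- V * rowSums(g[[i]] * g[[j]])
    k <- k + 1L
  }
  list(V = V, gdot = gdot)
}

# Turn an element-major E x 16 block matrix into a CSR value vector on
# `pattern`, accumulating in double or (for the native single-precision
# assembly comparison mode) in float, in element index order.
assemble_on_pattern <- function(pattern, blocks, precision) {
  vals <- accumulate_csr(pattern$pos - 1L, as.vector(t(blocks)),
                         pattern$nnz, precision == "single")
  sparse_system(pattern$row_ptr, pattern$col_ind, vals, pattern$n,
                precision)
}

#' Assemble the diffusion stiffness matrix K
#'
#' \eqn{K_{ij} = \sum_k \kappa_k \int_\Omega u_k \nabla u_i \cdot
#' \nabla u_j \, dr}: the P1 stiffness matrix with the element-wise mean
#' of the nodal diffusion coefficient as weight (for linear elements
#' \eqn{\int u_k = V/4}).
#'
#' @param mesh a [tet_mesh()].
#' @param kappa nodal diffusion coefficient, mm, length `N` (scalar
#'   recycled), all positive.
#' @param pattern optional precomputed sparsity pattern (internal reuse).
#' @param precision `"double"` (default) or `"single"` for the native
#'   single-precision assembly comparison mode, in which element
#'   contributions are accumulated in float in element index order.
#' @return A [sparse_system()].
#' @export
assemble_stiffness <- function(mesh, kappa, pattern = NULL,
                               precision = "double") {
  kappa <- rep_len(as.numeric(kappa), mesh$n_nodes)
  if (length(kappa) != mesh$n_nodes) stop("kappa length mismatch")
  if (any(kappa <= 0)) stop("kappa must be positive")
  if (is.null(pattern)) pattern <- csr_pattern(mesh)
  geo <- element_geometry(mesh)
  kbar <- rowMeans(matrix(kappa[mesh$elements], ncol = 4L))
  assemble_on_pattern(pattern, kbar * geo$gdot, precision)
}

#' Assemble the absorption mass matrix C
#'
#' \eqn{C_{ij} = \sum_k \mu_{a,k} \int_\Omega u_k u_i u_j \, dr}, exact
#' for P1 elements via the closed-form triple products (`V/20`, `V/60`,
#' `V/120` by index coincidence).
#'
#' @param mesh a [tet_mesh()].
#' @param mua nodal absorption coefficient, mm^-1 (scalar recycled),
#'   nonnegative (zero is admitted so that a pure-scattering limit can be
#'   assembled).
#' @inheritParams assemble_stiffness
#' @return A [sparse_system()].
#' @export
assemble_absorption <- function(mesh, mua, pattern = NULL,
                                precision = "double") {
  mua <- rep_len(as.numeric(mua), mesh$n_nodes)
  if (any(mua < 0)) stop("mua must be nonnegative")
  if (is.null(pattern)) pattern <- csr_pattern(mesh)
  V <- element_volumes(mesh)
  mu <- matrix(mua[mesh$elements], ncol = 4L)
  musum <- rowSums(mu)
  blocks <- matrix(0, nrow(mesh$elements), 16L)
  k <- 1L
  for (i in 1:4) for (j in 1:4) {
    blocks[, k] <- if (i == j) V * (mu[, i] / 30 + musum / 60)
                   else V * ((mu[, i] + mu[, j]) / 120 + musum / 120)
    k <- k + 1L
  }
  assemble_on_pattern(pattern, blocks, precision)
}

#' Assemble the boundary mass matrix A
#'
#' \eqn{A_{ij} = \int_{\partial\Omega} u_i u_j \, d\xi} over the boundary
#' triangles (`S/6` diagonal, `S/12` off-diagonal per face of area `S`).
#' Assembled on the full mesh sparsity pattern so it can be combined
#' value-wise with the volume matrices; rows of interior nodes are zero.
#'
#' @param mesh a [tet_mesh()] with a nonempty boundary.
#' @inheritParams assemble_stiffness
#' @return A [sparse_system()].
#' @export
assemble_boundary <- function(mesh, pattern = NULL, precision = "double") {
  bf <- mesh$boundary_faces
  if (is.null(bf) || nrow(bf) == 0L) stop("mesh has no boundary faces")
  if (is.null(pattern)) pattern <- csr_pattern(mesh)
  S <- face_areas(mesh)
  ii <- rep(1:3, each = 3L)
  jj <- rep.int(1:3, 3L)
  blocks <- matrix(0, nrow(bf), 9L)
  for (k in 1:9)
    blocks[, k] <- if (ii[k] == jj[k]) S / 6 else S / 12
  I <- as.vector(t(bf[, ii, drop = FALSE]))
  J <- as.vector(t(bf[, jj, drop = FALSE]))
  pos <- pattern_slots(pattern, I, J)
  vals <- accumulate_csr(pos - 1L, as.vector(t(blocks)), pattern$nnz,
                         precision == "single")
  sparse_system(pattern$row_ptr, pattern$col_ind, vals, pattern$n,
                precision)
}

#' Assemble the scaled mass matrix B
#'
#' \eqn{B_{ij} = (1/c) \int_\Omega u_i u_j \, dr} with `c` the speed of
#' light in the medium (mm/ps); symmetric positive definite.
#'
#' @param mesh a [tet_mesh()].
#' @param c speed of light in the medium, mm/ps, positive.
#' @inheritParams assemble_stiffness
#' @return A [sparse_system()].
#' @export
assemble_mass <- function(mesh, c, pattern = NULL, precision = "double") {
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    stop("c must be a positive scalar")
  if (is.null(pattern)) pattern <- csr_pattern(mesh)
  V <- element_volumes(mesh)
  blocks <- matrix(0, nrow(mesh$elements), 16L)
  ii <- rep(1:4, each = 4L)
  jj <- rep.int(1:4, 4L)
  for (k in 1:16)
    blocks[, k] <- if (ii[k] == jj[k]) V / (10 * c) else V / (20 * c)
  assemble_on_pattern(pattern, blocks, precision)
}

#' Combine the FEM matrices into the system matrix
#'
#' \eqn{S(\omega) = K + C + \gamma A + i\omega B}; real when
#' \eqn{\omega = 0} (the steady-state / time-domain matrix
#' \eqn{\tilde S = K + C + \gamma A}), complex symmetric (not Hermitian)
#' otherwise. All inputs must share one sparsity pattern. If any input
#' carries the `"single"` precision tag the combined real/imaginary
#' values are rounded to single precision and the result is tagged
#' accordingly.
#'
#' @param K,C,A,B assembled [sparse_system()] matrices on a common
#'   pattern.
#' @param gamma exitance scale \eqn{c/(2\zeta)}, mm/ps.
#' @param omega angular modulation frequency, rad/ps (0 for CW).
#' @return A [sparse_system()]; complex-valued when `omega != 0`.
#' @export
assemble_system <- function(K, C, A, B, gamma, omega = 0) {
  single <- any(c(K$precision, C$precision, A$precision, B$precision) ==
                "single")
  Sre <- sp_combine(list(K, C, A), list(1, 1, gamma))
  if (omega == 0) {
    if (single)
      Sre <- sparse_system(Sre$row_ptr, Sre$col_ind,
                           round_to_single(Sre$values), Sre$n, "single")
    return(Sre)
  }
  im <- omega * B$values
  re <- Sre$values
  if (single) {
    re <- round_to_single(re)
    im <- round_to_single(im)
  }
  S <- sparse_system(Sre$row_ptr, Sre$col_ind, complex(real = re,
                                                       imaginary = im),
                     Sre$n, "double")
  S$precision <- if (single) "single" else "double"
  S
}

#' Assemble a boundary source vector Q
#'
#' Projects a nodal source density `q` on the boundary onto the P1 basis
#' through the boundary-face mass integrals:
#' \eqn{Q_i = \int_{\partial\Omega} q^h u_i \, d\xi}, so that
#' \eqn{\sum_i Q_i = \int_{\partial\Omega} q^h d\xi} exactly. `q` must
#' vanish on interior nodes; by default a nonzero interior coefficient is
#' an error (set `on_interior = "ignore"` to drop such coefficients with
#' a warning).
#'
#' @param mesh a [tet_mesh()].
#' @param q nodal source coefficients, length `N`, supported on boundary
#'   nodes.
#' @param on_interior `"error"` (default) or `"ignore"`.
#' @return Numeric source vector of length `N`.
#' @export
assemble_source <- function(mesh, q, on_interior = c("error", "ignore")) {
  on_interior <- match.arg(on_interior)
  q <- as.numeric(q)
  stopifnot(length(q) == mesh$n_nodes)
  bnodes <- unique(as.vector(mesh$boundary_faces))
  interior_nz <- setdiff(which(q != 0), bnodes)
  if (length(interior_nz)) {
    if (on_interior == "error")
      stop("source coefficient nonzero on interior node ", interior_nz[1L])
    warning("ignoring source coefficients on ", length(interior_nz),
            " interior nodes")
    q[interior_nz] <- 0
  }
  bf <- mesh$boundary_faces
  S <- face_areas(mesh)
  qf <- matrix(q[bf], ncol = 3L)
  qsum <- rowSums(qf)
  Q <- numeric(mesh$n_nodes)
  for (k in 1:3) {
    contrib <- S * (qf[, k] + qsum) / 12
    acc <- rowsum(contrib, group = bf[, k])
    idx <- as.integer(rownames(acc))
    Q[idx] <- Q[idx] + acc[, 1L]
  }
  Q
}

#' Assemble all forward-model matrices at once
#'
#' Convenience wrapper building `K`, `C`, `A`, `B` on a shared sparsity
#' pattern, plus the combined system matrix `S(omega)` and the real part
#' `Stilde = K + C + gamma A` used by the time-domain iteration.
#'
#' @param mesh a [tet_mesh()].
#' @param params an [optical_params()].
#' @param omega angular modulation frequency, rad/ps.
#' @param assembly_precision `"double"` (production path) or `"single"`
#'   (native single-precision assembly, for the mixed-precision
#'   comparison only).
#' @return List with `K`, `C`, `A`, `B`, `S`, `Stilde`, `gamma`,
#'   `pattern`.
#' @export
assemble_forward <- function(mesh, params, omega = 0,
                             assembly_precision = "double") {
  stopifnot(inherits(params, "optical_params"),
            params$n_nodes == mesh$n_nodes)
  pattern <- csr_pattern(mesh)
  K <- assemble_stiffness(mesh, params$kappa, pattern, assembly_precision)
  C <- assemble_absorption(mesh, params$mua, pattern, assembly_precision)
  A <- assemble_boundary(mesh, pattern, assembly_precision)
  B <- assemble_mass(mesh, params$c, pattern, assembly_precision)
  Stilde <- sp_combine(list(K, C, A), list(1, 1, params$gamma))
  if (assembly_precision == "single")
    Stilde <- demote_precision(Stilde)
  S <- assemble_system(K, C, A, B, params$gamma, omega)
  list(K = K, C = C, A = A, B = B, S = S, Stilde = Stilde,
       gamma = params$gamma, pattern = pattern)
}

#' Convert a modulation frequency in MHz to angular rad/ps
#'
#' `100 MHz` maps to \eqn{2\pi \cdot 10^{-4}} rad/ps; all assembly is in
#' mm/ps units.
#'
#' @param mhz modulation frequency in MHz.
#' @return Angular frequency in rad/ps.
#' @export
omega_from_mhz <- function(mhz) 2 * pi * mhz * 1e-6
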