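#' Source and detector specifications
#'
#' An optode sits on the domain surface at `position` (mm; snapped to the
#' boundary) and carries either a `"gaussian"` surface profile of width
#' `sigma` (mm) or a `"point"` profile. A literal nodal delta makes
#' results mesh-dependent, so the default profile is a Gaussian of
#' `sigma = 2` mm; `"point"` maps to nodal injection (sources) or lumped
#' nodal sampling (detectors) for users who want it.
#'
#' @param position length-3 numeric position in mm.
#' @param profile `"gaussian"` or `"point"`.
#' @param sigma Gaussian width in mm (ignored for point profiles).
#' @return An object of class `optode_spec`.
#' @export
source_spec <- function(position, profile = c("gaussian", "point"),
                        sigma = 2) {
  profile <- match.arg(profile)
  stopifnot(length(position) == 3L, is.numeric(position))
  if (profile == "gaussian") stopifnot(sigma > 0)
  structure(list(position = as.numeric(position), profile = profile,
                 sigma = sigma, role = "source"), class = "optode_spec")
}

#' @rdname source_spec
#' @export
detector_spec <- function(position, profile = c("gaussian", "point"),
                          sigma = 2) {
  s <- source_spec(position, profile, sigma)
  s$role <- "detector"
  s
}

# Boundary node indices and their lumped surface measure l_i = int u_i dxi
# (row sums of the boundary load integrals).
boundary_lump <- function(mesh) {
  bf <- mesh$boundary_faces
  S <- face_areas(mesh)
  lump <- numeric(mesh$n_nodes)
  for (k in 1:3) {
    acc <- rowsum(S / 3, group = bf[, k])
    idx <- as.integer(rownames(acc))
    lump[idx] <- lump[idx] + acc[, 1L]
  }
  lump
}

# Snap an optode to the boundary: nearest boundary node, refused beyond
# twice the local edge length.
snap_to_boundary <- function(mesh, position) {
  bnodes <- sort(unique(as.vector(mesh$boundary_faces)))
  bxyz <- mesh$nodes[bnodes, , drop = FALSE]
  d2 <- (bxyz[, 1L] - position[1L])^2 + (bxyz[, 2L] - position[2L])^2 +
    (bxyz[, 3L] - position[3L])^2
  k <- which.min(d2)
  # local edge scale from the first boundary face containing the node
  bf <- mesh$boundary_faces
  frow <- which(bf[, 1L] == bnodes[k] | bf[, 2L] == bnodes[k] |
                bf[, 3L] == bnodes[k])[1L]
  verts <- mesh$nodes[bf[frow, ], , drop = FALSE]
  edge <- max(sqrt(rowSums((verts[c(2L, 3L, 1L), ] - verts)^2)))
  if (sqrt(d2[k]) > 2 * edge)
    stop(sprintf("optode at (%.3g, %.3g, %.3g) is %.3g mm from the surface (max snap distance %.3g mm)",
                 position[1L], position[2L], position[3L], sqrt(d2[k]),
                 2 * edge))
  list(node = bnodes[k], point = bxyz[k, ], distance = sqrt(d2[k]))
}

# Nodal coefficients of an optode's surface profile, normalised to unit
# boundary integral (int q^h dxi = 1); zero on interior nodes. Point
# profiles return NULL (handled by lumped nodal injection/sampling).
profile_coefficients <- function(mesh, spec, lump = boundary_lump(mesh)) {
  snap <- snap_to_boundary(mesh, spec$position)
  if (spec$profile == "point")
    return(list(q = NULL, node = snap$node))
  bnodes <- which(lump > 0)
  q <- numeric(mesh$n_nodes)
  d2 <- rowSums((mesh$nodes[bnodes, , drop = FALSE] -
                 matrix(snap$point, length(bnodes), 3L, byrow = TRUE))^2)
  q[bnodes] <- exp(-d2 / (2 * spec$sigma^2))
  total <- sum(q * lump)
  if (total <= 0) stop("degenerate optode profile")
  list(q = q / total, node = snap$node)
}

# Right-hand-side vector for one source.
source_vector <- function(mesh, spec, lump = boundary_lump(mesh)) {
  pc <- profile_coefficients(mesh, spec, lump)
  if (is.null(pc$q)) {
    Q <- numeric(mesh$n_nodes)
    Q[pc$node] <- 1
    Q
  } else {
    assemble_source(mesh, pc$q)
  }
}

# Projection weight vector for one detector: w with y = gamma * Phi' w.
detector_vector <- function(mesh, spec, A, lump = boundary_lump(mesh)) {
  pc <- profile_coefficients(mesh, spec, lump)
  if (is.null(pc$q)) {
    w <- numeric(mesh$n_nodes)
    w[pc$node] <- lump[pc$node]
    w
  } else {
    sp_matvec(A, pc$q)
  }
}

#' Solve the steady-state or frequency-domain forward problem
#'
#' Assembles the system matrix \eqn{S(\omega) = K + C + \gamma A +
#' i\omega B} and solves \eqn{S \Phi_i = Q_i} for every source. For
#' \eqn{\omega = 0} the system is real symmetric positive definite and is
#' solved with conjugate gradients; for \eqn{\omega > 0} it is complex
#' symmetric and solved with BiCGSTAB on the real 2Nx2N block expansion
#' (or in direct complex arithmetic with `strategy = "direct"`).
#'
#' @param mesh a [tet_mesh()].
#' @param params an [optical_params()].
#' @param sources list of [source_spec()] (a single spec is accepted).
#' @param omega angular modulation frequency, rad/ps (>= 0).
#' @param opts a [solver_options()].
#' @param strategy complex solve strategy, see [solve_complex()].
#' @param system optional precomputed [assemble_forward()] result.
#' @return An object of class `field_solution`: `phi` is an `N x
#'   n_sources` matrix of nodal photon-density coefficients (real for CW,
#'   complex otherwise), with per-source solve `reports`.
#' @export
solve_frequency <- function(mesh, params, sources, omega = 0,
                            opts = solver_options(),
                            strategy = c("expanded", "direct"),
                            system = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(omega >= 0)
  if (inherits(sources, "optode_spec")) sources <- list(sources)
  if (is.null(system)) system <- assemble_forward(mesh, params, omega)
  lump <- boundary_lump(mesh)
  ns <- length(sources)
  phi <- matrix(if (omega > 0) complex(1) else 0, mesh$n_nodes, ns)
  reports <- vector("list", ns)
  for (i in seq_len(ns)) {
    Q <- source_vector(mesh, sources[[i]], lump)
    if (omega == 0) {
      sol <- cg(system$Stilde, Q, opts)
    } else {
      sol <- solve_complex(system$S, as.complex(Q), opts, strategy)
    }
    phi[, i] <- sol$x
    reports[[i]] <- sol$report
  }
  structure(list(phi = phi, omega = omega, reports = reports,
                 gamma = params$gamma), class = "field_solution")
}

#' Boundary exitance
#'
#' Applies the Dirichlet-to-Neumann boundary operator
#' \eqn{\Gamma = (c / 2\zeta)\, \phi = \gamma \phi} on the boundary.
#' Returned as full-length nodal vectors (columns per source); only the
#' boundary-node entries carry physical meaning and only those enter the
#' measurement projection.
#'
#' @param field a `field_solution` from [solve_frequency()], or a nodal
#'   matrix/vector.
#' @param params an [optical_params()].
#' @return Matrix of nodal exitance values, same shape as the field.
#' @export
exitance <- function(field, params) {
  phi <- if (inherits(field, "field_solution")) field$phi else field
  params$gamma * phi
}

#' Project exitance onto detector profiles
#'
#' Evaluates \eqn{y_{ij} = \int_{\partial\Omega} \Gamma_i m_j \, d\xi}
#' with the boundary-face mass integrals for Gaussian profiles; a point
#' detector reduces to nodal sampling of the exitance weighted by the
#' node's lumped boundary measure.
#'
#' @param Gamma nodal exitance matrix (`N x n_sources`) from
#'   [exitance()].
#' @param detectors list of [detector_spec()].
#' @param mesh a [tet_mesh()].
#' @param A optional precomputed boundary matrix from
#'   [assemble_boundary()].
#' @return `n_sources x n_detectors` matrix of measurements.
#' @export
project <- function(Gamma, detectors, mesh, A = NULL) {
  if (inherits(detectors, "optode_spec")) detectors <- list(detectors)
  Gamma <- as.matrix(Gamma)
  if (is.null(A)) A <- assemble_boundary(mesh)
  lump <- boundary_lump(mesh)
  W <- vapply(detectors, function(d) detector_vector(mesh, d, A, lump),
              numeric(mesh$n_nodes))
  t(crossprod(W, Gamma))   # y[i, j] = Gamma_i . w_j
}

#' Log amplitude and phase of complex measurements
#'
#' \eqn{\ln A = \mathrm{Re}(\ln y)} and \eqn{\varphi = \mathrm{Im}(\ln
#' y)}, the standard frequency-domain data types. The phase is returned
#' on the principal branch \eqn{(-\pi, \pi]}; use [unwrap_phase()] along
#' a detector array ordered by distance when continuity matters.
#'
#' @param y complex (or positive real) measurement matrix; must be
#'   nonzero everywhere.
#' @return List with matrices `lnA` and `phase`.
#' @export
log_amp_phase <- function(y) {
  if (any(Mod(y) == 0)) stop("zero measurement has no logarithm")
  list(lnA = log(Mod(y)), phase = Arg(y))
}

#' Unwrap a phase sequence
#'
#' Removes 2-pi jumps from a phase series ordered along a line or
#' detector array, declaring the branch by continuity from the first
#' entry.
#'
#' @param phi numeric vector of wrapped phases (radians).
#' @return Unwrapped phases.
#' @export
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  phi - c(0, cumsum(round(d / (2 * pi)))) * 2 * pi
}

#' Full frequency-domain forward model
#'
#' Runs the solve-exitance-project pipeline for all sources and
#' detectors and converts to log amplitude and phase.
#'
#' @inheritParams solve_frequency
#' @param detectors list of [detector_spec()].
#' @return An object of class `measurement_set` with the complex (or
#'   real, for CW) `y` matrix (`n_sources x n_detectors`), `lnA`,
#'   `phase`, `omega` and per-source solver `reports`.
#' @export
forward_frequency <- function(mesh, params, sources, detectors,
                              omega = 0, opts = solver_options(),
                              strategy = c("expanded", "direct"),
                              system = NULL) {
  if (is.null(system)) system <- assemble_forward(mesh, params, omega)
  field <- solve_frequency(mesh, params, sources, omega, opts,
                           strategy, system)
  Gamma <- exitance(field, params)
  y <- project(Gamma, detectors, mesh, system$A)
  lp <- log_amp_phase(y)
  structure(list(y = y, lnA = lp$lnA, phase = lp$phase, omega = omega,
                 reports = field$reports), class = "measurement_set")
}

#' Standard 80-source / 80-detector cylinder optode layout
#'
#' Sources and detectors interleaved with equal angular spacing on two
#' rings of the cylinder mantle at one third and two thirds of the
#' height (z = -h/6 and +h/6 for a cylinder centred at the origin).
#'
#' @param radius cylinder radius, mm.
#' @param height cylinder height, mm.
#' @param n_sources,n_detectors optode counts (split evenly over the two
#'   rings).
#' @param profile,sigma optode profile passed to [source_spec()].
#' @return List with `sources` and `detectors` lists.
#' @export
optode_rings <- function(radius, height, n_sources = 80L,
                         n_detectors = 80L,
                         profile = "gaussian", sigma = 2) {
  ring_z <- c(-height / 6, height / 6)
  make <- function(n, ctor, offset) {
    per <- c(ceiling(n / 2), floor(n / 2))
    out <- list()
    for (r in 1:2) {
      if (per[r] == 0L) next
      ang <- 2 * pi * (seq_len(per[r]) - 1L) / per[r] + offset / per[r]
      for (a in ang)
        out[[length(out) + 1L]] <-
          ctor(c(radius * cos(a), radius * sin(a), ring_z[r]),
               profile = profile, sigma = sigma)
    }
    out
  }
  list(sources = make(n_sources, source_spec, 0),
       detectors = make(n_detectors, detector_spec, pi))
}
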