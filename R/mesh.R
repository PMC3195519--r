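#' Tetrahedral mesh
#'
#' Container for an unstructured tetrahedral mesh: node coordinates (mm),
#' element connectivity (4 nodes per tetrahedron) and oriented boundary
#' faces. Element vertex order is repaired on construction so that every
#' signed volume is positive; boundary faces are extracted from the
#' connectivity when not supplied and are oriented outward.
#'
#' @param nodes numeric `N x 3` matrix of coordinates in mm.
#' @param elements integer `E x 4` matrix of 1-based node indices.
#' @param boundary_faces optional integer `F x 3` matrix of 1-based node
#'   indices with outward orientation; extracted if `NULL`.
#' @param validate run full invariant checks (face-sharing counts, closed
#'   boundary surface). Disable for very large meshes built by the
#'   package's own generator.
#' @return An object of class `tet_mesh` with fields `nodes`, `elements`,
#'   `boundary_faces` and node count `n_nodes`.
#' @export
tet_mesh <- function(nodes, elements, boundary_faces = NULL,
                     validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(elements) == 4L)
  n <- nrow(nodes)
  if (any(elements < 1L) || any(elements > n))
    stop("element refers to a node index outside [1, N]")

  # orientation repair: swap last two vertices where signed volume < 0
  sv <- signed_volumes(nodes, elements)
  flip <- sv < 0
  if (any(flip))
    elements[flip, c(3L, 4L)] <- elements[flip, c(4L, 3L)]
  sv <- abs(sv)
  scale3 <- max(abs(nodes))^3 + 1
  if (any(sv <= 1e-14 * scale3))
    stop("degenerate (coplanar) element at index ",
         which(sv <= 1e-14 * scale3)[1L])

  mesh <- structure(list(nodes = nodes, elements = elements,
                         boundary_faces = NULL,
                         n_nodes = n), class = "tet_mesh")
  if (is.null(boundary_faces)) {
    mesh$boundary_faces <- extract_boundary(mesh)
  } else {
    boundary_faces <- as.matrix(boundary_faces)
    storage.mode(boundary_faces) <- "integer"
    stopifnot(ncol(boundary_faces) == 3L)
    if (any(boundary_faces < 1L) || any(boundary_faces > n))
      stop("boundary face refers to a node index outside [1, N]")
    mesh$boundary_faces <- boundary_faces
  }
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh: %d nodes, %d elements, %d boundary faces>\n",
              x$n_nodes, nrow(x$elements), nrow(x$boundary_faces)))
  invisible(x)
}

# Signed volume of each element, det of the edge matrix / 6.
signed_volumes <- function(nodes, elements) {
  a <- nodes[elements[, 1L], , drop = FALSE]
  e1 <- nodes[elements[, 2L], , drop = FALSE] - a
  e2 <- nodes[elements[, 3L], , drop = FALSE] - a
  e3 <- nodes[elements[, 4L], , drop = FALSE] - a
  (e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
   e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
   e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])) / 6
}

#' Element volume
#'
#' @param mesh a [tet_mesh()].
#' @param e element index (1-based).
#' @return Volume in mm^3 (positive by the mesh orientation convention).
#' @export
element_volume <- function(mesh, e) {
  stopifnot(e >= 1L, e <= nrow(mesh$elements))
  v <- signed_volumes(mesh$nodes, mesh$elements[e, , drop = FALSE])
  scale3 <- max(abs(mesh$nodes))^3 + 1
  if (abs(v) <= 1e-14 * scale3) stop("degenerate (coplanar) element")
  abs(v)
}

#' Element volumes for the whole mesh
#'
#' @param mesh a [tet_mesh()].
#' @return Vector of volumes in mm^3.
#' @export
element_volumes <- function(mesh) {
  abs(signed_volumes(mesh$nodes, mesh$elements))
}

# Constant P1 shape-function gradients for one element: a 4 x 3 matrix.
element_gradients <- function(mesh, e) {
  v <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
  J <- rbind(v[2L, ] - v[1L, ], v[3L, ] - v[1L, ], v[4L, ] - v[1L, ])
  Jinv <- solve(J)
  g <- t(Jinv)            # rows: grad lambda_2..4
  rbind(-colSums(g), g)
}

#' Exact local finite-element integrals for one tetrahedron
#'
#' Closed-form integrals of products of linear (P1) shape functions over
#' the element, from the multinomial formula
#' \eqn{\int u_1^a u_2^b u_3^c u_4^d dV = 6V\, a!b!c!d!/(a+b+c+d+3)!}.
#' The weighted mass block \eqn{\int u_k u_i u_j} equals `V/20` when
#' `k == i == j`, `V/60` when exactly two indices coincide and `V/120`
#' when all differ; the unweighted mass \eqn{\int u_i u_j} is `V/10` on
#' the diagonal and `V/20` off it.
#'
#' @param mesh a [tet_mesh()].
#' @param e element index.
#' @return A list with `volume`, the 4x4 `stiffness` block
#'   \eqn{V \nabla u_i \cdot \nabla u_j} (mm), the 4x4x4 `weighted_mass`
#'   array indexed `[k, i, j]` (mm^3) and the 4x4 `mass` block (mm^3).
#' @export
local_integrals <- function(mesh, e) {
  V <- element_volume(mesh, e)
  g <- element_gradients(mesh, e)
  stiff <- V * (g %*% t(g))
  wm <- array(V / 120, c(4L, 4L, 4L))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    eq <- (k == i) + (k == j) + (i == j)
    if (eq == 3L) wm[k, i, j] <- V / 20
    else if (eq == 1L) wm[k, i, j] <- V / 60
  }
  mass <- matrix(V / 20, 4L, 4L)
  diag(mass) <- V / 10
  list(volume = V, stiffness = stiff, weighted_mass = wm, mass = mass)
}

# Areas of the boundary faces (vectorized).
face_areas <- function(mesh, faces = mesh$boundary_faces) {
  a <- mesh$nodes[faces[, 1L], , drop = FALSE]
  u <- mesh$nodes[faces[, 2L], , drop = FALSE] - a
  v <- mesh$nodes[faces[, 3L], , drop = FALSE] - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Exact local integrals for one boundary face
#'
#' Closed-form P1 integrals over a boundary triangle of area `S` from the
#' 2-D multinomial formula
#' \eqn{\int u_1^a u_2^b u_3^c dA = 2S\, a!b!c!/(a+b+c+2)!}:
#' \eqn{\int u_i\,d\xi = S/3}; \eqn{\int u_i u_j\,d\xi = S/6} for
#' `i == j` and `S/12` otherwise.
#'
#' @param mesh a [tet_mesh()].
#' @param f boundary face index.
#' @return List with `area` (mm^2), 3x3 `mass` block (mm^2) and length-3
#'   `load` vector (mm^2).
#' @export
face_integrals <- function(mesh, f) {
  stopifnot(f >= 1L, f <= nrow(mesh$boundary_faces))
  S <- face_areas(mesh, mesh$boundary_faces[f, , drop = FALSE])
  scale2 <- max(abs(mesh$nodes))^2 + 1
  if (S <= 1e-14 * scale2) stop("zero-area boundary face")
  mass <- matrix(S / 12, 3L, 3L)
  diag(mass) <- S / 6
  list(area = S, mass = mass, load = rep(S / 3, 3L))
}

# Key encoding a sorted node triple; exact for N^3 < 2^53.
face_key <- function(tri, n) {
  a <- as.numeric(tri[, 1L]); b <- as.numeric(tri[, 2L])
  cc <- as.numeric(tri[, 3L])
  lo <- pmin(a, b, cc); hi <- pmax(a, b, cc)
  mid <- a + b + cc - lo - hi
  (lo * n + mid) * n + hi
}

#' Extract the boundary surface of a mesh
#'
#' Boundary faces are exactly those triangular faces adjacent to a single
#' element; they are returned with outward orientation (normal pointing
#' away from the owning element).
#'
#' @param mesh a [tet_mesh()] (its stored `boundary_faces` are ignored).
#' @return Integer `F x 3` matrix of 1-based node indices.
#' @export
extract_boundary <- function(mesh) {
  el <- mesh$elements
  n <- mesh$n_nodes
  # the four faces of each element, with the omitted (opposite) vertex
  fidx <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  faces <- do.call(rbind, lapply(1:4, function(k) el[, fidx[k, ], drop = FALSE]))
  opp <- c(el[, 1L], el[, 2L], el[, 3L], el[, 4L])
  keys <- face_key(faces, n)
  ord <- order(keys)
  ks <- keys[ord]
  m <- length(ks)
  same_prev <- c(FALSE, ks[-1L] == ks[-m])
  same_next <- c(same_prev[-1L], FALSE)
  runs <- rle(same_prev)  # a face in > 2 elements gives >= 2 TRUEs in a row
  if (any(runs$values & runs$lengths > 1L))
    stop("inconsistent connectivity: face shared by > 2 elements")
  sel <- ord[!same_prev & !same_next]
  bf <- faces[sel, , drop = FALSE]
  bopp <- opp[sel]
  # orient outward: normal of (a, b, c) must point away from the opposite
  # vertex of the owning element
  a <- mesh$nodes[bf[, 1L], , drop = FALSE]
  u <- mesh$nodes[bf[, 2L], , drop = FALSE] - a
  v <- mesh$nodes[bf[, 3L], , drop = FALSE] - a
  nx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  ny <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  nz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  w <- a - mesh$nodes[bopp, , drop = FALSE]
  inward <- nx * w[, 1L] + ny * w[, 2L] + nz * w[, 3L] < 0
  if (any(inward))
    bf[inward, c(2L, 3L)] <- bf[inward, c(3L, 2L)]
  bf
}

#' Validate mesh invariants
#'
#' Checks that all node indices are in range, all signed volumes are
#' positive, each interior face is shared by exactly two elements and
#' each boundary face by one, and that the boundary surface is closed
#' (every boundary edge shared by exactly two boundary faces).
#'
#' @param mesh a [tet_mesh()].
#' @return Invisibly `TRUE`; stops on the first violated invariant.
#' @export
validate_mesh <- function(mesh) {
  n <- mesh$n_nodes
  el <- mesh$elements
  if (any(el < 1L) || any(el > n)) stop("element node index out of range")
  if (any(signed_volumes(mesh$nodes, el) <= 0))
    stop("element with non-positive signed volume")
  fidx <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  faces <- do.call(rbind, lapply(1:4, function(k) el[, fidx[k, ], drop = FALSE]))
  ks <- sort(face_key(faces, n))
  cnt <- rle(ks)$lengths
  if (any(cnt > 2L)) stop("face shared by more than two elements")
  bkeys <- sort(face_key(mesh$boundary_faces, n))
  ekeys <- rle(ks)$values[cnt == 1L]
  if (length(bkeys) != length(ekeys) || any(bkeys != ekeys))
    stop("stored boundary faces do not match the faces adjacent to one element")
  # closed surface: boundary edges each shared by exactly two faces
  bf <- mesh$boundary_faces
  ed <- rbind(bf[, c(1L, 2L)], bf[, c(2L, 3L)], bf[, c(3L, 1L)])
  ekey <- pmin(ed[, 1L], ed[, 2L]) * as.numeric(n) + pmax(ed[, 1L], ed[, 2L])
  if (any(rle(sort(ekey))$lengths != 2L))
    stop("boundary surface is not closed")
  invisible(TRUE)
}

# --- deterministic cylinder mesh -------------------------------------------

# Triangulated unit-disk layout ("spider web"): centre node plus nr rings,
# ring j carrying 6j equally spaced nodes. Returns node xy coordinates and
# CCW triangles (1-based).
disk_triangulation <- function(nr, radius) {
  ring_start <- function(j) if (j == 0L) 1L else 2L + 3L * j * (j - 1L)
  xs <- 0; ys <- 0
  for (j in seq_len(nr)) {
    k <- 0:(6L * j - 1L)
    ang <- 2 * pi * k / (6 * j)
    xs <- c(xs, radius * j / nr * cos(ang))
    ys <- c(ys, radius * j / nr * sin(ang))
  }
  tris <- matrix(0L, 0L, 3L)
  for (j in seq_len(nr)) {
    so <- ring_start(j); no <- 6L * j
    si <- ring_start(j - 1L); ni <- if (j == 1L) 1L else 6L * (j - 1L)
    tri <- vector("list", 6L)
    for (s in 0:5) {
      o <- so + (s * j + 0:j) %% no
      i <- if (j == 1L) rep(1L, 2L) else si + (s * (j - 1L) + 0:(j - 1L)) %% ni
      up <- cbind(o[1:j], o[2:(j + 1L)], i[1:j])
      down <- if (j >= 2L)
        cbind(i[1:(j - 1L)], o[2:j], i[2:j])
      else matrix(0L, 0L, 3L)
      tri[[s + 1L]] <- rbind(up, down)
    }
    tris <- rbind(tris, do.call(rbind, tri))
  }
  list(x = xs, y = ys, triangles = tris)
}

# Split the prism (b1 b2 b3 | t1 t2 t3) into three tetrahedra with face
# diagonals chosen through the globally smallest vertex index of each quad
# face, so adjacent prisms always agree on shared faces.
split_prism <- function(b, t) {
  r <- which.min(b)
  ord <- ((r - 1L) + 0:2) %% 3L + 1L
  w <- c(b[ord], t[ord])         # w[1] is the smallest bottom vertex
  if (min(w[2L], w[6L]) < min(w[3L], w[5L])) {
    rbind(c(w[1L], w[2L], w[3L], w[6L]),
          c(w[1L], w[2L], w[6L], w[5L]),
          c(w[1L], w[5L], w[6L], w[4L]))
  } else {
    rbind(c(w[1L], w[2L], w[3L], w[5L]),
          c(w[1L], w[5L], w[3L], w[6L]),
          c(w[1L], w[5L], w[6L], w[4L]))
  }
}

#' Deterministic synthetic cylinder mesh
#'
#' Builds a structured tetrahedral mesh of a cylinder of the given radius
#' and height (axis along z, centred at the origin) by triangulating a
#' disk into concentric rings, extruding it into prism layers and
#' splitting every prism into three tetrahedra with a consistent
#' smallest-index diagonal rule. The construction uses no randomness and
#' no external mesher: identical arguments give byte-identical meshes.
#'
#' @param radius cylinder radius in mm.
#' @param height cylinder height in mm.
#' @param resolution target edge length in mm; must satisfy
#'   `0 < resolution < radius`. Smaller values refine the mesh.
#' @return A [tet_mesh()].
#' @export
#' @examples
#' m <- generate_cylinder_mesh(25, 50, 10)
#' sum(element_volumes(m)) / (pi * 25^2 * 50)  # close to 1
generate_cylinder_mesh <- function(radius, height, resolution) {
  stopifnot(radius > 0, height > 0)
  if (resolution <= 0 || resolution >= radius)
    stop("resolution must lie in (0, radius)")
  nr <- max(1L, as.integer(round(radius / resolution)))
  nz <- as.integer(round(height / resolution))
  if (nz < 1L)
    stop("resolution too coarse to form any element along the axis")
  disk <- disk_triangulation(nr, radius)
  nd <- length(disk$x)
  zs <- seq(-height / 2, height / 2, length.out = nz + 1L)
  nodes <- cbind(rep(disk$x, nz + 1L), rep(disk$y, nz + 1L),
                 rep(zs, each = nd))
  ntri <- nrow(disk$triangles)
  elems <- matrix(0L, 3L * ntri * nz, 4L)
  row <- 1L
  for (l in seq_len(nz)) {
    off_b <- (l - 1L) * nd
    off_t <- l * nd
    for (k in seq_len(ntri)) {
      tri <- disk$triangles[k, ]
      tets <- split_prism(tri + off_b, tri + off_t)
      elems[row:(row + 2L), ] <- tets
      row <- row + 3L
    }
  }
  tet_mesh(nodes, elems, validate = FALSE)
}

# --- native mesh I/O --------------------------------------------------------

#' Read a mesh from the native text format
#'
#' The native format is plain text: a header line `N E F`, then `N` node
#' lines `x y z`, `E` element lines of four 0-based node indices and `F`
#' boundary-face lines of three 0-based indices.
#'
#' @param path file path.
#' @return A [tet_mesh()].
#' @export
read_mesh <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- scan(con, integer(), n = 3L, quiet = TRUE)
  n <- hdr[1L]; e <- hdr[2L]; f <- hdr[3L]
  nodes <- matrix(scan(con, double(), n = 3L * n, quiet = TRUE), n, 3L,
                  byrow = TRUE)
  elems <- matrix(scan(con, integer(), n = 4L * e, quiet = TRUE), e, 4L,
                  byrow = TRUE) + 1L
  bf <- matrix(scan(con, integer(), n = 3L * f, quiet = TRUE), f, 3L,
               byrow = TRUE) + 1L
  tet_mesh(nodes, elems, boundary_faces = bf, validate = FALSE)
}

#' Write a mesh in the native text format
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [read_mesh()] for the format description.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d %d", mesh$n_nodes, nrow(mesh$elements),
                     nrow(mesh$boundary_faces)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1L],
                     mesh$nodes[, 2L], mesh$nodes[, 3L]), con)
  e <- mesh$elements - 1L
  writeLines(sprintf("%d %d %d %d", e[, 1L], e[, 2L], e[, 3L], e[, 4L]), con)
  b <- mesh$boundary_faces - 1L
  writeLines(sprintf("%d %d %d", b[, 1L], b[, 2L], b[, 3L]), con)
  invisible(path)
}

#' Export a mesh as legacy ASCII VTK (for visualisation)
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.vtk` path.
#' @param point_data optional named list of per-node numeric vectors.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  n <- mesh$n_nodes; e <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0", "dotfem mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1L],
                     mesh$nodes[, 2L], mesh$nodes[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", e, 5L * e), con)
  el <- mesh$elements - 1L
  writeLines(sprintf("4 %d %d %d %d", el[, 1L], el[, 2L], el[, 3L],
                     el[, 4L]), con)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  writeLines(rep("10", e), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Interpolate a nodal field at arbitrary points
#'
#' Locates each query point in the mesh and evaluates the P1 interpolant
#' of the nodal field there (barycentric-weighted sum over the containing
#' element's vertices).
#'
#' @param mesh a [tet_mesh()].
#' @param field numeric or complex vector of nodal values, length `N`.
#' @param points `M x 3` matrix of query coordinates (mm).
#' @return Vector of `M` interpolated values.
#' @export
interpolate_field <- function(mesh, field, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  stopifnot(length(field) == mesh$n_nodes)
  loc <- locate_points_tet(mesh$nodes, mesh$elements - 1L, points, 1e-9)
  if (any(loc$elem < 0L))
    stop("point outside mesh: index ", which(loc$elem < 0L)[1L])
  out <- vector(mode = if (is.complex(field)) "complex" else "numeric",
                nrow(points))
  for (p in seq_len(nrow(points))) {
    vi <- mesh$elements[loc$elem[p] + 1L, ]
    out[p] <- sum(loc$bary[p, ] * field[vi])
  }
  out
}
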