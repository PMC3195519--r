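# Independent oracles and small fixtures shared across the suite.

# Closed-form multinomial integrals of barycentric monomials:
# over a tetrahedron of volume V:
#   int u1^a u2^b u3^c u4^d dV = 6V a! b! c! d! / (a+b+c+d+3)!
# over a triangle of area S:
#   int u1^a u2^b u3^c dA = 2S a! b! c! / (a+b+c+2)!
tet_monomial <- function(a, b, c, d, V) {
  6 * V * factorial(a) * factorial(b) * factorial(c) * factorial(d) /
    factorial(a + b + c + d + 3)
}
tri_monomial <- function(a, b, c, S) {
  2 * S * factorial(a) * factorial(b) * factorial(c) /
    factorial(a + b + c + 2)
}

# Gauss-Legendre nodes/weights on [0, 1] by Golub-Welsch.
gauss01 <- function(n) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = 2 * (e$vectors[1, ]^2) / 2)
}

# High-order quadrature of f(lambda1..lambda4) over the reference
# tetrahedron (volume 1/6) via the Duffy transform; exact for
# polynomials well beyond degree 2n - 4.
quad_tet <- function(f, n = 10) {
  g <- gauss01(n)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    u <- g$x[i]; v <- g$x[j]; w <- g$x[k]
    x <- u
    y <- v * (1 - u)
    z <- w * (1 - u) * (1 - v)
    jac <- (1 - u)^2 * (1 - v)
    lam <- c(1 - x - y - z, x, y, z)
    total <- total + g$w[i] * g$w[j] * g$w[k] * jac * f(lam)
  }
  total
}

# Quadrature over the reference triangle (area 1/2), Duffy transform.
quad_tri <- function(f, n = 12) {
  g <- gauss01(n)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- g$x[i]; v <- g$x[j]
    x <- u
    y <- v * (1 - u)
    jac <- 1 - u
    lam <- c(1 - x - y, x, y)
    total <- total + g$w[i] * g$w[j] * jac * f(lam)
  }
  total
}

# Fixtures -------------------------------------------------------------

unit_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1))
}

two_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1)),
           rbind(1:4, c(2, 3, 4, 5)))
}

# Small cylinders, memoised per resolution so repeated tests stay fast.
.mesh_cache <- new.env(parent = emptyenv())
cyl_mesh <- function(resolution, radius = 25, height = 50) {
  key <- paste0("m", radius, "_", height, "_", resolution)
  if (is.null(.mesh_cache[[key]]))
    .mesh_cache[[key]] <- generate_cylinder_mesh(radius, height, resolution)
  .mesh_cache[[key]]
}

# Dense matrix of a sparse system (wrapper for readability).
densify <- function(S) as.matrix(S)

# Infinite-medium diffusion Green's function for a CW point source.
greens_cw <- function(r, mua, kappa) {
  mu_eff <- sqrt(mua / kappa)
  exp(-mu_eff * r) / (4 * pi * kappa * r)
}

cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
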