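#' Iterative solver options
#'
#' @param tolerance relative residual target, `||b - Sx|| / ||b||` in the
#'   2-norm, checked against the true (recomputed) residual on
#'   convergence.
#' @param max_iterations iteration cap (>= 1).
#' @param stall_window early-termination guard: stop (reason
#'   `"stagnated"`) when the best residual seen has not improved by at
#'   least 0.1 percent over this many consecutive iterations — the
#'   round-off floor of the arithmetic has been reached. The best
#'   iterate found is returned.
#' @param preconditioner `"diagonal"` (Jacobi) or `"none"`.
#' @param precision `"double"` or `"single"`. In single precision all
#'   matrix-vector arithmetic and vector updates are performed in IEEE
#'   single precision (scalar reductions are accumulated in double).
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(tolerance = 1e-10, max_iterations = 5000L,
                           preconditioner = c("diagonal", "none"),
                           precision = c("double", "single"),
                           stall_window = 250L) {
  stopifnot(tolerance > 0, max_iterations >= 1, stall_window >= 10)
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 preconditioner = match.arg(preconditioner),
                 precision = match.arg(precision),
                 stall_window = as.integer(stall_window)),
            class = "solver_options")
}

#' Reference CPU array backend
#'
#' The iterative solvers are written against a small abstract array
#' interface (sparse mat-vec, dot product, axpy, norm, elementwise
#' divide, precision demotion), so that an accelerator backend with the
#' copy-in / solve / copy-out data flow can be substituted without
#' touching the solver logic. This is the reference CPU implementation.
#' With `precision = "single"`, mat-vec products run in single-precision
#' arithmetic and every vector result is rounded to single-precision
#' storage; dot products are accumulated in double.
#'
#' @param precision `"double"` or `"single"`.
#' @return A list of backend functions.
#' @export
cpu_backend <- function(precision = c("double", "single")) {
  precision <- match.arg(precision)
  dm <- if (precision == "single") {
    function(x) if (is.complex(x)) x else round_to_single(x)
  } else identity
  list(
    precision = precision,
    matvec = function(S, x) sp_matvec(S, x),
    dot = function(x, y) sum(Conj(x) * y),
    axpy = function(a, x, y) dm(a * x + y),
    scale = function(a, x) dm(a * x),
    ewdiv = function(x, d) dm(x / d),
    norm2 = function(x) sqrt(sum(Mod(x)^2)),
    demote = dm
  )
}

#' Diagonal (Jacobi) preconditioner
#'
#' Returns a preconditioner applying \eqn{v \mapsto v / \mathrm{diag}(S)}.
#'
#' @param S a [sparse_system()]; all diagonal entries must be nonzero
#'   (nonzero modulus in the complex case).
#' @return A list with an `apply(v)` function and the diagonal.
#' @export
diagonal_preconditioner <- function(S) {
  d <- sp_diag(S)
  if (any(Mod(d) == 0)) stop("zero diagonal entry; cannot precondition")
  list(apply = function(v) v / d, diag = d)
}

# Diagonal preconditioning is realised as symmetric Jacobi equilibration:
# the system is transformed once to D^{-1/2} S D^{-1/2} (D^{1/2} x) =
# D^{-1/2} b with D = |diag(S)|, which preserves symmetry (and positive
# definiteness), is algebraically the split form of the Jacobi
# preconditioner, and — crucially for the mixed-precision path — is
# applied in double precision BEFORE any demotion to single, so the
# single-precision solver sees an equilibrated matrix with unit-modulus
# diagonal and far smaller dynamic range.
equilibrate <- function(S, b) {
  d <- Mod(sp_diag(S))
  if (any(d == 0)) stop("zero diagonal entry; cannot precondition")
  sc <- 1 / sqrt(d)
  rows <- rep.int(seq_len(S$n), diff(S$row_ptr))
  vals <- S$values * sc[rows] * sc[S$col_ind + 1L]
  list(S = sparse_system(S$row_ptr, S$col_ind, vals, S$n, S$precision),
       b = b * sc, scale = sc)
}

solve_report <- function(iterations, residual, reason) {
  structure(list(iterations = iterations, residual = residual,
                 reason = reason), class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("<solve_report: %s after %d iterations, residual %.3e>\n",
              x$reason, x$iterations, x$residual))
  invisible(x)
}

# Apply preconditioning (equilibration) in double precision, then demote
# for the single-precision path. Returns the transformed system plus the
# scale needed to recover x.
prepare_system <- function(S, b, opts) {
  scale <- NULL
  if (opts$preconditioner == "diagonal") {
    eq <- equilibrate(S, b)
    S <- eq$S; b <- eq$b; scale <- eq$scale
  }
  if (opts$precision == "single") {
    if (is.complex(S$values))
      stop("single-precision solves use the real 2Nx2N expansion; ",
           "expand the complex system first")
    S <- sparse_system(S$row_ptr, S$col_ind, round_to_single(S$values),
                       S$n, "single")
    b <- round_to_single(b)
  }
  list(S = S, b = b, scale = scale)
}

true_residual <- function(S, x, b, bnorm, backend)
  backend$norm2(backend$axpy(-1, backend$matvec(S, x), b)) / bnorm

#' Preconditioned conjugate-gradient solver
#'
#' Solves `S x = b` for a real symmetric positive definite sparse system
#' by conjugate gradients. The `"diagonal"` preconditioner is applied in
#' its split (symmetric equilibration) form: the system is transformed
#' once to \eqn{D^{-1/2} S D^{-1/2}} with `D = |diag(S)|` in double
#' precision — before any demotion to single — and the solution is
#' rescaled on return; the reported residual refers to the equilibrated
#' system the iteration actually sees. The convergence test uses the
#' recurrence residual, but convergence is only declared once the true
#' residual `||b - Sx|| / ||b||`, recomputed from scratch, meets the
#' tolerance. Breakdown (zero, negative or non-finite
#' curvature) is detected and reported; the iterate with the smallest
#' residual seen so far is returned rather than crashing or silently
#' returning a wrong answer.
#'
#' @param S a real [sparse_system()], symmetric positive definite.
#' @param b right-hand side vector.
#' @param opts a [solver_options()].
#' @param backend array backend; defaults to the CPU backend at the
#'   requested precision.
#' @return List with the solution `x` and `report` (a solve report with
#'   `iterations`, final true `residual` and `reason` among
#'   `"converged"`, `"max_iterations"`, `"breakdown"`).
#' @export
cg <- function(S, b, opts = solver_options(),
               backend = cpu_backend(opts$precision)) {
  stopifnot(inherits(S, "sparse_system"), length(b) == S$n)
  ps <- prepare_system(S, b, opts)
  S <- ps$S; b <- ps$b
  bnorm <- backend$norm2(b)
  if (bnorm == 0)
    return(list(x = numeric(S$n), report = solve_report(0L, 0, "converged")))

  x <- numeric(S$n)
  r <- b
  p <- r
  rz <- backend$dot(r, r)
  best_x <- x; best_rn <- bnorm
  last_gain <- 0L
  reason <- "max_iterations"
  iter <- 0L
  while (iter < opts$max_iterations) {
    iter <- iter + 1L
    q <- backend$matvec(S, p)
    curv <- backend$dot(p, q)
    if (!is.finite(curv) || curv <= 0) { reason <- "breakdown"; break }
    alpha <- rz / curv
    x <- backend$axpy(alpha, p, x)
    r <- backend$axpy(-alpha, q, r)
    rn <- backend$norm2(r)
    if (!is.finite(rn)) { reason <- "breakdown"; break }
    if (rn < best_rn) {
      if (rn < 0.999 * best_rn) last_gain <- iter
      best_rn <- rn; best_x <- x
    }
    if (iter - last_gain > opts$stall_window) { reason <- "stagnated"; break }
    if (rn / bnorm <= opts$tolerance) {
      # verify outside the recurrence before declaring convergence
      rt <- backend$axpy(-1, backend$matvec(S, x), b)
      r <- rt
      rn <- backend$norm2(rt)
      if (rn / bnorm <= opts$tolerance) { reason <- "converged"; break }
      rz <- backend$dot(r, r)
      p <- r
      next
    }
    rz_new <- backend$dot(r, r)
    p <- backend$axpy(rz_new / rz, p, r)
    rz <- rz_new
  }
  finalize_solve(S, b, bnorm, x, best_x, iter, reason, opts, backend,
                 ps$scale)
}

finalize_solve <- function(S, b, bnorm, x, best_x, iter, reason, opts,
                           backend, scale = NULL) {
  res_x <- true_residual(S, x, b, bnorm, backend)
  res_best <- true_residual(S, best_x, b, bnorm, backend)
  if (!is.finite(res_x) || res_best < res_x) {
    x <- best_x
    res_x <- res_best
  }
  if (!reason %in% c("breakdown", "stagnated"))
    reason <- if (res_x <= opts$tolerance) "converged" else "max_iterations"
  if (reason == "stagnated" && res_x <= opts$tolerance)
    reason <- "converged"
  if (!is.null(scale)) x <- scale * x
  list(x = x, report = solve_report(iter, res_x, reason))
}

#' Preconditioned BiCGSTAB solver
#'
#' Solves `S x = b` for a square nonsingular (real or complex) sparse
#' system with the biconjugate gradient stabilised method and optional
#' Jacobi preconditioning. The breakdown scalars (shadow product rho and
#' stabilisation step omega near zero, or any non-finite intermediate)
#' trigger early termination of the iteration loop — such conditions do
#' occur in practice, in particular under single-precision round-off —
#' and the best iterate by true residual is returned with a breakdown
#' report.
#'
#' @inheritParams cg
#' @return As [cg()].
#' @export
bicgstab <- function(S, b, opts = solver_options(),
                     backend = cpu_backend(opts$precision)) {
  stopifnot(inherits(S, "sparse_system"), length(b) == S$n)
  ps <- prepare_system(S, b, opts)
  S <- ps$S; b <- ps$b
  bnorm <- backend$norm2(b)
  zero <- if (is.complex(S$values) || is.complex(b))
    complex(S$n) else numeric(S$n)
  if (bnorm == 0)
    return(list(x = zero, report = solve_report(0L, 0, "converged")))

  x <- zero
  r <- b
  r0 <- r
  rho <- 1; alpha <- 1; omega <- 1
  v <- zero; p <- zero
  best_x <- x; best_rn <- bnorm
  last_gain <- 0L
  eps_break <- 1e-30
  reason <- "max_iterations"
  iter <- 0L
  while (iter < opts$max_iterations) {
    iter <- iter + 1L
    rho_new <- backend$dot(r0, r)
    if (!is.finite(Mod(rho_new)) || Mod(rho_new) < eps_break * bnorm^2) {
      reason <- "breakdown"; break
    }
    beta <- (rho_new / rho) * (alpha / omega)
    p <- backend$axpy(beta, backend$axpy(-omega, v, p), r)
    v <- backend$matvec(S, p)
    den <- backend$dot(r0, v)
    if (!is.finite(Mod(den)) || Mod(den) < eps_break * bnorm^2) {
      reason <- "breakdown"; break
    }
    alpha <- rho_new / den
    s <- backend$axpy(-alpha, v, r)
    sn <- backend$norm2(s)
    if (!is.finite(sn)) { reason <- "breakdown"; break }
    if (sn / bnorm <= opts$tolerance) {
      x <- backend$axpy(alpha, p, x)
      rt <- backend$axpy(-1, backend$matvec(S, x), b)
      rn <- backend$norm2(rt)
      if (rn < best_rn) {
        if (rn < 0.999 * best_rn) last_gain <- iter
        best_rn <- rn; best_x <- x
      }
      if (rn / bnorm <= opts$tolerance) { reason <- "converged"; break }
      r <- rt; rho <- rho_new
      next
    }
    t <- backend$matvec(S, s)
    tt <- backend$dot(t, t)
    if (!is.finite(Mod(tt)) || Mod(tt) < eps_break) {
      reason <- "breakdown"; break
    }
    omega <- backend$dot(t, s) / tt
    if (!is.finite(Mod(omega)) || Mod(omega) < eps_break) {
      reason <- "breakdown"; break
    }
    x <- backend$axpy(omega, s, backend$axpy(alpha, p, x))
    r <- backend$axpy(-omega, t, s)
    rn <- backend$norm2(r)
    if (!is.finite(rn)) { reason <- "breakdown"; break }
    if (rn < best_rn) {
      if (rn < 0.999 * best_rn) last_gain <- iter
      best_rn <- rn; best_x <- x
    }
    if (iter - last_gain > opts$stall_window) { reason <- "stagnated"; break }
    if (rn / bnorm <= opts$tolerance) {
      rt <- backend$axpy(-1, backend$matvec(S, x), b)
      rn2 <- backend$norm2(rt)
      if (rn2 / bnorm <= opts$tolerance) { reason <- "converged"; break }
      r <- rt
    }
    rho <- rho_new
  }
  finalize_solve(S, b, bnorm, x, best_x, iter, reason, opts, backend,
                 ps$scale)
}

#' Expand a complex system into its real 2Nx2N block form
#'
#' The complex system `S x = Q` is rewritten as the real block system
#' \deqn{\begin{bmatrix} S_{re} & -S_{im} \\ S_{im} & S_{re}
#' \end{bmatrix} \begin{bmatrix} x_{re} \\ x_{im} \end{bmatrix} =
#' \begin{bmatrix} Q_{re} \\ Q_{im} \end{bmatrix},}
#' which a real (and in particular a single-precision) solver can
#' process. Recombine the solution with [complex_recombine()].
#'
#' @param S a complex [sparse_system()].
#' @param Q complex right-hand side of length `S$n`.
#' @return List with the real `2N x 2N` [sparse_system()] `S2` and the
#'   real right-hand side `b2`.
#' @export
complex_expand <- function(S, Q) {
  stopifnot(is.complex(S$values), length(Q) == S$n)
  n <- S$n
  nnz_row <- diff(S$row_ptr)
  rows <- rep.int(seq_len(n), nnz_row)
  re <- Re(S$values); im <- Im(S$values)
  # top block rows: [Re, -Im]; bottom: [Im, Re]
  r2 <- c(rows, rows)
  c2 <- c(S$col_ind, S$col_ind + n)
  vtop <- c(re, -im)
  vbot <- c(im, re)
  o <- order(r2, c2)
  col_sorted <- c2[o]
  row_ptr_half <- c(0L, cumsum(2L * nnz_row))
  S2 <- sparse_system(
    row_ptr = c(row_ptr_half, row_ptr_half[-1L] + row_ptr_half[n + 1L]),
    col_ind = c(col_sorted, col_sorted),
    values = c(vtop[o], vbot[o]),
    n = 2L * n, precision = "double")
  list(S2 = S2, b2 = c(Re(Q), Im(Q)))
}

#' Recombine the solution of an expanded system
#'
#' @param x2 real solution vector of length `2N` from the expanded
#'   system.
#' @return Complex vector `x2[1:N] + i x2[N + (1:N)]`.
#' @export
complex_recombine <- function(x2) {
  n <- length(x2) %/% 2L
  complex(real = x2[seq_len(n)], imaginary = x2[n + seq_len(n)])
}

#' Solve a complex sparse system
#'
#' Default strategy expands the complex system to its real 2Nx2N block
#' form and runs BiCGSTAB on it (the form a single-precision real solver
#' consumes); `strategy = "direct"` runs BiCGSTAB in complex arithmetic
#' instead, as an independent cross-check. The two agree within solver
#' tolerance.
#'
#' @param S complex [sparse_system()].
#' @param Q complex right-hand side.
#' @param opts a [solver_options()].
#' @param strategy `"expanded"` (default) or `"direct"`.
#' @return List with complex `x` and `report`.
#' @export
solve_complex <- function(S, Q, opts = solver_options(),
                          strategy = c("expanded", "direct")) {
  strategy <- match.arg(strategy)
  if (strategy == "direct") {
    if (opts$precision == "single")
      stop("direct complex solves are double precision only")
    return(bicgstab(S, Q, opts))
  }
  # demotion to single (after equilibration) happens inside the solver
  ex <- complex_expand(S, Q)
  sol <- bicgstab(ex$S2, ex$b2, opts)
  list(x = complex_recombine(sol$x), report = sol$report)
}
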