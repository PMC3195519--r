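#' Finite-difference time-stepping scheme
#'
#' One-parameter theta family of time integrators for the time-domain
#' diffusion problem: `theta = 0` explicit, `theta = 0.5`
#' Crank-Nicolson, `theta = 1` implicit Euler. Step lengths are in ps.
#' The explicit range `theta < 0.5` is only conditionally stable and is
#' accepted with a warning; the geometric step-growth policy (longer
#' steps on the exponentially decaying tail) requires the
#' unconditionally stable implicit scheme `theta = 1`.
#'
#' @param theta control parameter in `[0, 1]`.
#' @param dt base step length, ps (> 0).
#' @param n_steps number of steps (>= 1).
#' @param policy `"fixed"` or `"geometric"` step adaptivity.
#' @param growth geometric growth factor (> 1), applied after the
#'   detected signal peak.
#' @return An object of class `time_scheme`.
#' @export
time_scheme <- function(theta = 0.5, dt = 50, n_steps = 100L,
                        policy = c("fixed", "geometric"), growth = 1.05) {
  policy <- match.arg(policy)
  stopifnot(theta >= 0, theta <= 1, dt > 0, n_steps >= 1)
  if (policy == "geometric") {
    if (theta < 1)
      stop("geometric step growth requires the unconditionally stable ",
           "implicit scheme (theta = 1)")
    stopifnot(growth > 1)
  }
  if (theta < 0.5)
    warning("theta < 0.5 is only conditionally stable; the step length ",
            "is limited by the fastest decaying mode")
  structure(list(theta = theta, dt = dt, n_steps = as.integer(n_steps),
                 policy = policy, growth = growth),
            class = "time_scheme")
}

#' Next step length under an adaptivity policy
#'
#' The fixed policy keeps the base step. The geometric policy multiplies
#' the step by the growth factor once the detected signal has passed its
#' global peak and is decaying: the last five samples must be positive
#' and strictly decreasing and the current sample below 80 percent of
#' the peak, so that early near-zero samples (where the discrete delta
#' response only carries scheme ringing and solver noise) cannot trigger
#' spurious growth. Before the peak the step is unchanged.
#'
#' @param signal_history numeric vector of detected signal samples so
#'   far (e.g. the total detected intensity per step).
#' @param dt current step length, ps.
#' @param scheme a [time_scheme()].
#' @return The next step length in ps.
#' @export
adapt_steps <- function(signal_history, dt, scheme) {
  if (scheme$policy == "fixed") return(scheme$dt)
  n <- length(signal_history)
  if (n < 5L) return(dt)
  peak <- max(signal_history)
  win <- signal_history[(n - 4L):n]
  decaying <- all(win > 0) && all(diff(win) < 0) &&
    win[5L] < 0.8 * peak && which.max(signal_history) <= n - 4L
  if (decaying) dt * scheme$growth else dt
}

#' Run the time-domain forward model
#'
#' Propagates the delta-pulse response by the theta-scheme iteration
#' \deqn{[\theta \tilde S + B/\Delta t_0]\,\Phi(t_0) = Q_0 / \Delta t_0,}
#' \deqn{[\theta \tilde S + B/\Delta t_n]\,\Phi(t_n) =
#'   -[(1-\theta)\tilde S - B/\Delta t_n]\,\Phi(t_{n-1}),}
#' with \eqn{\tilde S = K + C + \gamma A} and mass matrix `B`. Each step
#' solves a symmetric positive definite system with conjugate gradients;
#' the diagonal preconditioner is cached while the step length is
#' unchanged and rebuilt when it grows. The detector projection
#' \eqn{y_{ij}(t_n) = \gamma \int \Gamma_i m_j} is applied at every step.
#' Times are `t_n = sum of steps up to n` (so a fixed 50 ps grid reads
#' 50, 100, ..., ps); with the theta-scheme delta initialisation the
#' profile stored at `t_n` approximates the continuous response at
#' `t_n - (1 - theta) dt`, which [tpsf_times()] exposes for convergence
#' studies.
#'
#' @param mesh a [tet_mesh()].
#' @param params an [optical_params()].
#' @param sources,detectors optode lists ([source_spec()],
#'   [detector_spec()]).
#' @param scheme a [time_scheme()].
#' @param opts a [solver_options()] for the per-step CG solves.
#' @param system optional precomputed [assemble_forward()] result (with
#'   `omega = 0`).
#' @return An object of class `tpsf`: array `y[n_sources, n_detectors,
#'   n_steps]` of detected intensities, step times `times` (ps), step
#'   lengths `dts`, the scheme, and the per-step CG iteration summary.
#' @export
run_time_domain <- function(mesh, params, sources, detectors, scheme,
                            opts = solver_options(tolerance = 1e-10),
                            system = NULL) {
  stopifnot(inherits(scheme, "time_scheme"))
  if (inherits(sources, "optode_spec")) sources <- list(sources)
  if (inherits(detectors, "optode_spec")) detectors <- list(detectors)
  if (is.null(system)) system <- assemble_forward(mesh, params, omega = 0)
  St <- system$Stilde
  B <- system$B
  lump <- boundary_lump(mesh)
  Qs <- vapply(sources, function(s) source_vector(mesh, s, lump),
               numeric(mesh$n_nodes))
  W <- vapply(detectors, function(d) detector_vector(mesh, d, system$A,
                                                     lump),
              numeric(mesh$n_nodes))
  ns <- length(sources); nd <- length(detectors); nt <- scheme$n_steps
  y <- array(0, c(ns, nd, nt))
  dts <- numeric(nt)
  times <- numeric(nt)
  iters <- matrix(0L, ns, nt)

  # An adaptive schedule is driven by the total detected signal of the
  # first source and shared by all sources so the TPSF array has one
  # common time grid.
  th <- scheme$theta
  for (i in seq_len(ns)) {
    dt <- if (i == 1L) scheme$dt else dts[1L]
    lhs <- sp_combine(list(St, B), list(th, 1 / dt))
    phi <- NULL
    t_now <- 0
    sig <- numeric(0)
    for (n in seq_len(nt)) {
      if (i == 1L) dts[n] <- dt
      rhs <- if (n == 1L) Qs[, i] / dt
             else sp_matvec(B, phi) / dt - (1 - th) * sp_matvec(St, phi)
      sol <- cg(lhs, rhs, opts)
      if (sol$report$reason != "converged")
        stop("CG failed to converge at time step ", n, " (residual ",
             format(sol$report$residual, digits = 3), ")")
      phi <- sol$x
      iters[i, n] <- sol$report$iterations
      t_now <- t_now + dt
      times[n] <- t_now
      y[i, , n] <- params$gamma * as.vector(crossprod(W, phi))
      sig <- c(sig, sum(y[i, , n]))
      dt_next <- if (i == 1L) adapt_steps(sig, dt, scheme)
                 else if (n < nt) dts[n + 1L] else dt
      if (dt_next != dt) {
        dt <- dt_next
        lhs <- sp_combine(list(St, B), list(th, 1 / dt))
      }
    }
  }
  structure(list(y = y, times = times, dts = dts, scheme = scheme,
                 iterations = iters), class = "tpsf")
}

#' Effective sample times of a temporal point-spread function
#'
#' The theta-scheme with the first-step delta injection yields, at
#' the n-th stored step, a second-order-accurate approximation of the
#' continuous impulse response at `t_n - (1 - theta) dt_n`. These
#' effective times are the right abscissae for convergence studies and
#' cross-grid comparison.
#'
#' @param tpsf a `tpsf` from [run_time_domain()].
#' @return Numeric vector of effective times, ps.
#' @export
tpsf_times <- function(tpsf) {
  tpsf$times - (1 - tpsf$scheme$theta) * tpsf$dts
}

#' Temporal point-spread function summaries
#'
#' Total detected intensity \eqn{E = \sum_n y(t_n) \Delta t_n} and mean
#' time of flight \eqn{\langle t \rangle = \sum_n t_n y(t_n) \Delta t_n
#' / E} for one source-detector pair.
#'
#' @param y numeric vector of sampled intensities, or a `tpsf` (then
#'   `source`, `detector` select the pair).
#' @param dts step lengths (taken from the `tpsf` if one is given).
#' @param times sample times (idem; effective times via [tpsf_times()]).
#' @param source,detector pair indices when `y` is a `tpsf`.
#' @return List with `total` and `mean_time` (ps).
#' @export
tpsf_moments <- function(y, dts = NULL, times = NULL, source = 1L,
                         detector = 1L) {
  if (inherits(y, "tpsf")) {
    obj <- y
    y <- obj$y[source, detector, ]
    dts <- obj$dts
    times <- tpsf_times(obj)
  }
  stopifnot(length(y) >= 1L, length(dts) == length(y),
            length(times) == length(y))
  E <- sum(y * dts)
  if (E == 0) stop("zero total intensity: moments undefined")
  list(total = E, mean_time = sum(times * y * dts) / E)
}
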