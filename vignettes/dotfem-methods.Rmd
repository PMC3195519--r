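---
title: "Methods: the dotfem forward solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dotfem forward solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Light propagating through a highly scattering medium such as biological
tissue is well described by the diffusion approximation to the radiative
transfer equation. `dotfem` solves, on a compact domain $\Omega$ with
boundary $\partial\Omega$,

$$\left[-\nabla\cdot\kappa(\mathbf r)\nabla + \mu_a(\mathbf r) +
\frac{i\omega}{c}\right]\hat\phi(\mathbf r,\omega) = 0,$$

for the (complex) photon density $\hat\phi$, where $\mu_a$ is the
absorption coefficient (mm$^{-1}$), $\kappa = [3(\mu_a+\mu_s)]^{-1}$ the
diffusion coefficient (mm) with reduced scattering $\mu_s$, $c$ the speed
of light in the medium, and $\omega$ the angular source modulation
frequency ($\omega = 0$ is the steady-state / continuous-wave case; the
time-domain equation replaces $i\omega/c$ by $c^{-1}\partial_t$). A
Robin boundary condition couples the field to the source distribution
$q$ on the surface,

$$\phi(\xi) + 2\zeta(n)\,\kappa(\xi)\frac{\partial\phi}{\partial\nu}
 = q(\xi),\qquad \xi\in\partial\Omega,$$

with $\zeta$ a reflectance term encoding the refractive-index mismatch
at the tissue–air interface. The measurable quantity is the exitance
$\Gamma = (c/2\zeta)\,\phi \equiv \gamma\phi$ on the boundary,
integrated against detector profiles $m_j$:
$y_{ij} = \int_{\partial\Omega}\Gamma_i\,m_j\,d\xi$, reported as
log amplitude $\ln A = \mathrm{Re}(\ln y)$ and phase
$\varphi = \mathrm{Im}(\ln y)$.

**Units.** Lengths are mm, times ps, $c_0 = 0.2998$ mm/ps,
$c = c_0/n$. Modulation frequencies given in MHz convert as
$100\,\mathrm{MHz} \to 2\pi\cdot10^{-4}$ rad/ps.

**The $\zeta(n)$ convention.** There is no single canonical closed form
for $\zeta$. `optical_params()` accepts an explicit value; when none is
given it uses the Groenhuis polynomial fit for the effective internal
reflection coefficient,
$R_\text{eff} = -1.440/n^2 + 0.710/n + 0.668 + 0.0636\,n$ and
$\zeta = (1+R_\text{eff})/(1-R_\text{eff})$ (about 3.25 at $n = 1.4$).
Which convention was used is recorded in every run manifest, so results
are reproducible regardless of the default.

## Discretisation

The domain is divided into linear (P1) tetrahedral elements with $N$
vertex nodes; field and parameters are expanded in the nodal hat basis
$u_i$. Galerkin projection yields the sparse complex-symmetric system

$$S(\omega)\,\Phi = Q,\qquad
  S = K(\{\kappa_i\}) + C(\{\mu_{a,i}\}) + \gamma A + i\omega B,$$

with the stiffness, absorption-mass, boundary-mass and mass matrices
assembled from exact closed-form P1 integrals (the multinomial formula
$\int u_1^au_2^bu_3^cu_4^d\,dV = 6V\,a!b!c!d!/(a+b+c+d+3)!$ and its 2-D
analogue). P1 elements keep every local integral closed-form and are the
standard choice for this class of solver; quadrature is used only as a
test oracle. The source vector is the boundary-mass projection of the
nodal source profile, $Q_i = \int_{\partial\Omega} q^h u_i\,d\xi$, which
makes source injection and detector projection exactly adjoint and hence
the measurement matrix reciprocal ($y_{ij} = y_{ji}$ for swapped
identical profiles) up to solver tolerance.

All four matrices are assembled on one shared CSR sparsity pattern (the
element connectivity graph), so their combination into $S$ is value-wise
and exactly reconstructible. Assembly always accumulates element
contributions in double precision; a single-precision matrix is obtained
by rounding the finished values (`demote_precision()`). A
native-single-precision assembly mode exists purely as a comparison arm
of the precision study: accumulating float contributions in element
order loses digits where many elements meet at a vertex, which is
precisely the effect the study quantifies.

**Optode profiles.** A literal nodal delta makes sources
mesh-dependent, so the default "point" source is a Gaussian surface
profile of $\sigma = 2$ mm, normalised to unit boundary integral;
`profile = "point"` gives plain nodal injection (sources) or lumped
nodal sampling (detectors) for users who want it. Optodes snap to the
nearest boundary node and are refused beyond twice the local edge
length.

## Linear solvers

Steady-state and time-stepping systems are real symmetric positive
definite and solved with conjugate gradients; frequency-domain systems
are complex symmetric and solved by BiCGSTAB, by default on the real
block expansion
$\bigl[\begin{smallmatrix}S_\text{re}&-S_\text{im}\\
S_\text{im}&S_\text{re}\end{smallmatrix}\bigr]$
of the $N\times N$ complex system into a $2N\times2N$ real one (the form
a single-precision real solver consumes); a direct complex-arithmetic
BiCGSTAB is kept as an independent cross-check and the two must agree
within tolerance.

Design choices that matter:

* **Tolerance** is the relative true residual $\|b - Sx\|_2/\|b\|_2$.
  The recurrence residual only triggers a convergence *check*; the
  solver re-verifies with a from-scratch residual before declaring
  success.
* **Diagonal preconditioning is applied as symmetric Jacobi
  equilibration**: the system is transformed once to
  $D^{-1/2}SD^{-1/2}$ with $D = |\operatorname{diag} S|$, in double
  precision, *before* any demotion to single. Algebraically this is the
  split form of the Jacobi preconditioner; numerically it hands the
  single-precision solver a matrix with unit-modulus diagonal and small
  dynamic range. This matters a great deal: without it the
  single-precision error floor of the forward solution is roughly two
  orders of magnitude higher.
* **Early termination guards.** Breakdown scalars (non-positive CG
  curvature; BiCGSTAB $\rho$ or $\omega$ vanishing or non-finite) stop
  the iteration with a `breakdown` report instead of propagating NaNs —
  in single precision such conditions genuinely occur. In addition a
  stagnation guard ends the iteration (reason `stagnated`) when the
  best residual has not improved by 0.1 % over a window (default 250
  iterations): the arithmetic's round-off floor has been reached. In
  every abnormal termination the iterate with the smallest true
  residual seen is returned.
* **Backend contract.** Solver logic touches arrays only through a
  small interface (sparse mat-vec, dot, axpy, norm, demotion), supplied
  by `cpu_backend()`. The single-precision backend performs mat-vec
  products in IEEE float (compiled kernels) and rounds every vector
  update to float storage, while scalar reductions accumulate in
  double. An accelerator backend replicating the copy-in / solve /
  copy-out data flow can be substituted without touching solver code.

## Time domain

The temporal impulse response is computed by the $\theta$-scheme
iteration

$$[\theta\tilde S + B/\Delta t_0]\,\Phi(t_0) = Q_0/\Delta t_0,\qquad
[\theta\tilde S + B/\Delta t_n]\,\Phi(t_n) =
 -[(1-\theta)\tilde S - B/\Delta t_n]\,\Phi(t_{n-1}),$$

with $\tilde S = K + C + \gamma A$; $\theta = 1$ is implicit Euler
(unconditionally stable), $\theta = 0.5$ Crank–Nicolson, $\theta = 0$
explicit (accepted with a stability warning only). Each step is an SPD
CG solve; the equilibrated operator is cached while $\Delta t$ is
unchanged. Summing the iteration over all steps telescopes to
$\tilde S\,(\sum_n\Phi_n\Delta t) = Q$, so the time-integrated TPSF
reproduces the CW measurement exactly up to tail truncation — the 5 %
agreement the tests assert is limited only by grid coverage of the
decay.

Two discrete-delta subtleties are worth knowing. First, the first-step
injection $Q_0/\Delta t_0$ means the value stored at label
$t_n = \sum_{m\le n}\Delta t_m$ is a second-order approximation of the
continuous response at $t_n - (1-\theta)\Delta t_n$; `tpsf_times()`
exposes these effective times, and the grid-refinement study interpolates
on them (otherwise Crank–Nicolson would appear first-order through a
spurious half-step time shift). Second, Crank–Nicolson is not L-stable:
before the physical signal reaches a detector the projected TPSF rings
around zero with amplitude that can rival the (tiny) early true signal;
it is swamped as soon as the signal rises. Tests therefore assert
nonnegativity from the peak onward.

The adaptive step policy (allowed only with $\theta = 1$) multiplies
$\Delta t$ by a factor $g = 1.05$ by default once the detected total
signal has passed its peak: the guard requires the last five samples
positive, strictly decreasing, and below 80 % of the peak, so that
early ringing cannot trigger growth. An adaptive schedule is derived
from the first source and shared by all sources, keeping one common
time grid.

## The mixed-precision study

`run_precision_experiment()` solves the same frequency-domain problem
three ways: double assembly + double solve (reference, tolerance
$10^{-12}$); double assembly, values demoted to single, single solve;
and native single assembly + single solve. The field is interpolated at
100 uniform samples along the line from the source through the cylinder
axis to the antipodal mantle point, and $\Delta\ln A$ and
$\Delta\varphi$ (phase unwrapped along the line) are reported per point
together with the maxima of $|\Delta q|/|q_\text{ref}|$.

Definitions the numbers depend on:

* *Relative error* is pointwise $|q_s - q_d|/|q_d|$; samples within one
  local edge length of the source are excluded from the maxima (the
  source near field is mesh-dominated in any discretisation), as are
  points whose reference value underflows; exclusions are flagged in
  the report.
* The single-precision solves run at tolerance $10^{-9}$ — deliberately
  *below* the float round-off floor — so they terminate via the
  stagnation guard at their attainable floor. Measuring at a reachable
  tolerance (e.g. $10^{-6}$) would report solver truncation error, not
  the precision floor; and the floor itself is insensitive to further
  tolerance tightening, which the test suite checks.
* The default study fixture is the homogeneous cylinder of radius
  25 mm, height 50 mm at resolution 1.7 mm ($21\,630$ nodes,
  $117\,450$ elements), $\mu_a = 0.01$ mm$^{-1}$, $\kappa = 0.3$ mm,
  $\omega = 2\pi\cdot100$ MHz. This size keeps the full three-solve
  study at well under a minute while being deep into the regime where
  the assembly-mode ordering (double-assembled error below
  single-assembled error, errors growing with distance and with the
  optical coefficients) is unambiguous; on very coarse meshes those
  orderings are noise-dominated and not asserted.

## The synthetic cylinder generator

`generate_cylinder_mesh()` builds the study geometry deterministically:
a spider-web triangulation of the disk (concentric rings, ring $j$
carrying $6j$ nodes), extruded into prism layers, each prism split into
three tetrahedra with diagonals chosen through the globally smallest
vertex index of each quad face — a face-local rule, so adjacent prisms
always conform. Identical arguments give byte-identical meshes with no
external mesher and no randomness.

This emulates the regular cylinder fixtures used for forward-solver
studies: correct volume and surface within faceting error, valid
conforming connectivity, high-valence interior vertices (what makes the
single-assembly arm interesting). It does *not* emulate unstructured
meshes from a real mesher: element quality is uniform, node ordering is
regular, and exact rotational symmetry is (deliberately) broken only by
the index-based diagonal rule. Passing tests on this fixture therefore
validate the numerics and their precision behaviour, not robustness to
pathological element shapes.

## Problem sizes used by the test suite

Unit and property tests run on cylinders at resolutions 12–5 mm
(63–7 000 nodes), solver-oracle tests against dense factorisations on
meshes up to 500 nodes, physics-limit checks at 2.5 mm (6 951 nodes),
and the headline precision study at 1.7 mm (21 630 nodes). These sizes
were chosen so each check sits in the asymptotic regime it probes while
the whole suite stays interactive.

## Known limitations

* P1 elements only; no adaptivity, no higher-order or mixed elements.
* The discrete maximum principle is not guaranteed on coarse meshes:
  steady-state fields can dip slightly negative far from the source at
  4–8 mm resolutions; refine before interpreting tails.
* Heterogeneous parameters are supported nodally, but the cylinder
  fixture and all shipped studies are homogeneous.
* The geometric step policy shares one schedule across sources (driven
  by the first source's detected signal).
* No inverse problem, no radiative-transfer or Monte-Carlo reference
  model, and no GPU backend in-tree — the backend contract is the seam
  where one would attach.
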