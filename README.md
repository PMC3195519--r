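# dotfem

A finite-element forward solver for the diffusion approximation of
light transport in scattering tissue — the computational core of
diffuse optical tomography (DOT). DOT instruments shine near-infrared
light into tissue at surface positions and measure what emerges
elsewhere; reconstructing absorption and scattering maps from such data
requires solving the *forward* problem (predicting boundary
measurements from known optical parameters) many times over. `dotfem`
is that forward solver, for steady-state (CW), frequency-domain and
time-domain measurement systems, aimed at researchers prototyping DOT
methods and at anyone studying the numerics of mixed-precision FEM
solvers.

## The model

On a tetrahedral P1 finite-element mesh of the domain, the diffusion
equation with a Robin boundary condition discretises to the sparse
complex-symmetric system

```
S(ω) Φ = Q,      S = K({κᵢ}) + C({μₐ,ᵢ}) + γA + iωB,
```

where `K`, `C`, `A`, `B` are the stiffness, absorption-mass,
boundary-mass and mass matrices (exact closed-form P1 integrals, CSR
storage), `γ = c/2ζ` the exitance scale, and `ω` the angular modulation
frequency. Boundary measurements are `y_ij = ∫ Γ_i m_j dξ` with
exitance `Γ = γφ`, reported as log amplitude `ln A = Re(ln y)` and
phase `φ = Im(ln y)`. Time-domain responses come from the θ-scheme
iteration on `S̃ = K + C + γA` and `B`. Systems are solved in-package:
conjugate gradients for real SPD problems, BiCGSTAB for complex ones
(by default via the real 2N×2N block expansion), with diagonal
(Jacobi-equilibration) preconditioning, early-termination guards, and a
single-precision mode whose matrix-vector arithmetic runs in IEEE
float — the basis of the package's mixed-precision error study.

## Worked example

```r
library(dotfem)

## deterministic cylinder phantom: r = 25 mm, h = 50 mm
mesh <- generate_cylinder_mesh(radius = 25, height = 50, resolution = 2.5)
mesh
#> <tet_mesh: 6951 nodes, 36000 elements, 3600 boundary faces>

params <- optical_params(mesh, mua = 0.01, mus = 1)   # mm^-1
params
#> <optical_params: 6951 nodes, mua 0.01 mm^-1, kappa 0.33 mm, n = 1.4,
#>  zeta = 3.251 (fit), gamma = 0.03294 mm/ps>

## a 100 MHz modulated source and three detectors on the mantle
src  <- source_spec(c(25, 0, 0))
dets <- lapply(c(pi/2, pi, 3*pi/2), function(a)
  detector_spec(c(25*cos(a), 25*sin(a), 0)))
ms <- forward_frequency(mesh, params, src, dets,
                        omega = omega_from_mhz(100),
                        opts = solver_options(tolerance = 1e-10))
round(cbind(lnA = as.numeric(ms$lnA), phase = as.numeric(ms$phase)), 4)
#>           lnA   phase
#> [1,] -14.1068 -0.7783
#> [2,] -16.8832 -1.1896
#> [3,] -14.0975 -0.7764
```

The two detectors a quarter-turn from the source see nearly identical
signals (the small difference is the mesh's broken rotational
symmetry); the antipodal detector is ~e^2.8 dimmer and lags a further
0.41 rad — light takes longer to diffuse across the cylinder.

The mixed-precision study compares a single-precision forward solution
against the double-precision reference along a line through the
cylinder:

```r
rep <- run_precision_experiment(mesh, params, src)
rep
#> <precision_report>
#>   line samples: 100 (5 excluded near source/underflow)
#>   double-assembled: max rel err lnA 1.215e-07, phase 3.697e-06
#>   single-assembled: max rel err lnA 1.999e-07, phase 7.582e-07
```

i.e. for these moderate optical parameters, solving in single precision
perturbs log amplitude and phase only at the 1e-7–1e-6 relative level.

## Command line

A thin CLI over the same functions lives at `inst/cli/dotfem`
(`meshgen`, `forward`, `precision`, each driven by a YAML config plus
overrides); see `?read_config` for the schema and
`inst/extdata/example_config.yaml` for a starting point. Runs emit TSV
measurement tables plus a JSON manifest recording every parameter, the
ζ convention and per-source solver reports.

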