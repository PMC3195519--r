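Package: dotfem
Title: Finite-Element Forward Solver for Diffuse Optical Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A finite-element forward solver for the diffusion
    approximation of light transport in scattering tissue, as used in
    diffuse optical tomography. Supports steady-state (continuous-wave),
    frequency-domain and time-domain problems on unstructured tetrahedral
    meshes with linear (P1) elements and a Robin boundary condition.
    Provides a deterministic synthetic cylinder-mesh generator, sparse
    (CSR) system assembly, in-package conjugate-gradient and BiCGSTAB
    iterative solvers with diagonal preconditioning and early-termination
    guards, a real 2Nx2N expansion of the complex frequency-domain system,
    theta-scheme time stepping for temporal point-spread functions, and a
    mixed-precision study facility comparing single- and double-precision
    solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
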