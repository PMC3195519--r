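# Example dotfem run configuration.
#
#   dotfem meshgen   --config example_config.yaml
#   dotfem forward   --config example_config.yaml
#   dotfem precision --config example_config.yaml
mesh:
  source: generate       # generate | file
  radius: 25             # mm
  height: 50             # mm
  resolution: 2.5        # target edge length, mm
  path: cylinder.mesh    # meshgen output / file input

optics:
  mua: 0.01              # absorption, mm^-1
  mus: 1.0               # reduced scattering, mm^-1 (or give kappa directly)
  n_refr: 1.4            # refractive index; zeta derived unless given

optodes:
  n_sources: 80
  n_detectors: 80
  profile: gaussian
  sigma: 2               # mm

mode: frequency          # cw | frequency | time
omega_mhz: 100

time:                    # used in time mode
  theta: 0.5             # 0.5 = Crank-Nicolson, 1 = implicit Euler
  dt: 50                 # ps
  n_steps: 100
  policy: fixed          # fixed | geometric (geometric needs theta = 1)
  growth: 1.05

solver:
  tolerance: 1.0e-10
  max_iterations: 5000
  preconditioner: diagonal   # diagonal | none
  precision: double          # double | single
  strategy: expanded         # expanded | direct (complex solves)

precision:               # used by the precision command
  combination: i         # i | ii | iii preset mua/mus pairs
  n_samples: 100

output:
  dir: out
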