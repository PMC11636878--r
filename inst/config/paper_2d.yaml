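# Reference profile: the published 2D stenotic-channel study conditions.
# Every value here equals the package default; edit a copy to override.
seed: 1
output_dir: "."
geometry:
  R0: 0.05          # reference half-width, m
  x_center: 0.5     # Gaussian narrowing centre, m
  length: 1.0       # channel length, m
fluid:
  rho: 1000         # kg/m^3
  nu: 1.85e-6       # m^2/s
normalization:
  V_kg: 1
  V_m: 0.1          # inlet diameter 2*R0
  V_s: 10.811       # so V_m/V_s = u_max
inlet:
  u_max: 0.00925    # m/s
cases:
  A_range: [0.015, 0.035]
  sigma_range: [0.10, 0.18]
  n_A: 4
  n_sigma: 4
  validation_layout: [9, 5]
architecture:
  kind: mixed       # mixed | hypernetwork | modes
  main_widths: [856, 856, 856, 856]
  hyper_widths: []
  use_tsc: true
  include_case: true
  input_bias: true
  hyper_feature: 10
training:
  counts: {inlet: 160, outlet: 160, wall_top: 160, wall_bottom: 160, interior: 3200}
  iterations: 1000
  iterations_per_epoch: 1000
  pool_factor: 1000
  lr: 1.0e-3
  lr_min: 1.0e-5
  betas: [0.9, 0.999]
  weights: {w_physics: 1, w_bc: 1, w_derivative: 1}
  gpinn_phase: off
  trace_every: 50
evaluation:
  n_points: 10000
  n_wall: 200
wss_convention: as_printed
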