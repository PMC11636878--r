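# tubepinn

Multi-case physics-informed neural networks (PINNs) for steady,
incompressible 2D flow in stenotic channels.

Hemodynamic quantities such as pressure drop and wall shear stress in
narrowed (stenotic) vessels normally require one computational-fluid-dynamics
run per geometry. A *multi-case* PINN instead learns the whole family of
flows at once: a neural field `(u, v, p) = f(x, y; λ)` is trained — without
any labelled data — by minimizing the residuals of the governing equations
over a parameterized family of geometries, after which the flow in an unseen
geometry is a single forward pass. `tubepinn` implements this program for
the canonical test bed of a 2D channel with a Gaussian narrowing, for
researchers in physics-informed machine learning and computational
hemodynamics who want a fully inspectable, CPU-scale reference
implementation.

## Model

The channel occupies `x ∈ [0, 1] m`, `|y| ≤ R(x)` with half-width

    R(x) = R0 − A · exp(−(x − μ)² / (2σ²)),   R0 = 0.05 m, μ = 0.5 m,

and case parameters `λ = (A, σ)`, `A ∈ [0.015, 0.035] m`,
`σ ∈ [0.10, 0.18] m`. The flow satisfies the steady incompressible
Navier–Stokes equations

    ∇·u = 0,
    (u·∇)u = −(1/ρ)∇p + ν∇²u,

with `ρ = 1000 kg/m³`, `ν = 1.85×10⁻⁶ m²/s`, no-slip walls, a parabolic
inlet profile `u = u_max(1 − y²/R0²)`, `u_max = 0.00925 m/s`, and `p = 0` at
the outlet. The loss is the unit-normalized sum of mean-squared PDE
residuals and boundary mismatches (reference units 1 kg, 0.1 m, 10.811 s, so
every term is dimensionless and O(1)-comparable).

Three multi-case architectures over a SiLU fully connected backbone:

* **Mixed** — `λ` is appended to the coordinate inputs of one network;
* **Hypernetwork** — a side network `f_h(λ)` emits *all* weights and biases
  of the main network `f_m(x)`;
* **Modes** — DeepONet-style: `f_h(λ)` emits a `B × 3` modes array `ℳ`,
  `f_m(x)` emits mode weights `q`, and `ŷ_i = Σ_j q_j ℳ_ji`.

Two further strategies are first-class: **tube-specific coordinates** (TSC)
— eight derived inputs (centerline distance `c`, normalized width `L_n`,
wall-distance surrogate `d_sq = 1 − L_n²`, and their products) that encode
the tube geometry directly — and a **gradient-enhanced (gPINN) loss**
penalizing the squared derivatives of the normalized residuals with respect
to the (range-normalized) case parameters.

Because no automatic-differentiation backend is assumed, the package ships
its own derivative engine: a truncated-Taylor forward mode that carries
exact first/second/third-order derivative states of every neuron with
respect to coordinates and case parameters (including through the analytic
TSC features and through hypernetwork-generated weights), paired with a
hand-written reverse pass for trainable-parameter gradients. Every
derivative path is verified against central finite differences in the test
suite.

## Worked example

Train a small mixed network with TSC inputs on the straight channel
(`A = 0`, whose exact solution is plane Poiseuille flow) and measure its
error against the analytic reference:

```r
library(tubepinn)

spec <- network_spec("mixed", c(64, 64, 64), use_tsc = TRUE, include_case = FALSE)
count_parameters(spec)
#> [1] 9219

tc <- training_config(
  spec, cases = data.frame(A = 0, sigma = 0.134),
  counts = c(inlet = 32, outlet = 32, wall_top = 32, wall_bottom = 32, interior = 256),
  iterations = 4000, pool_factor = 100, lr = 2e-3, lr_min = 1e-5,
  trace_every = 800, seed = 3)
fit <- train_pinn(tc)   # a few minutes on one CPU
round(fit$trace[, c("step", "continuity", "momentum", "wall_noslip", "inlet_u", "total")], 5)
#>   step continuity momentum wall_noslip inlet_u   total
#> 1    1    0.04869  0.04757     0.00953 0.63276 0.75134
#> 2  800    0.00001  0.00001     0.00002 0.00000 0.00004
#> 3 1600    0.00000  0.00000     0.00000 0.00000 0.00001
#> 4 2400    0.00000  0.00000     0.00000 0.00000 0.00000
#> 5 3200    0.00000  0.00000     0.00000 0.00000 0.00000
#> 6 4000    0.00000  0.00000     0.00000 0.00000 0.00000

error_report(fit$model, analytic_straight_channel(), case_parameters(0, 0.134),
             n = 2000, seed = 1)
#> error_report (A = 0, sigma = 0.134, N = 2000): eps_u = 0.543%, eps_v = NA, eps_p = 4.136%, eps_WSS = 1.552%
```

The trace columns are the dimensionless loss terms (continuity, momentum,
wall no-slip, inlet profile mismatch); `eps_u` etc. are relative L2 errors
in percent against the exact solution — the axial velocity is recovered to
about half a percent. The analytic wall shear stress of this flow is
`μ·u_max/R0 = 3.4225e-4 Pa` under the symmetric-tensor convention:

```r
model_wall_shear_stress(analytic_straight_channel(), 0.5, "bottom",
                        case_parameters(0, 0.134))
#>      x        wss
#> ux 0.5 0.00034225
```

Exact parameter counting of the published architectures, and the 16
training / 45 validation case grid:

```r
count_parameters(network_spec("mixed", rep(856, 4), use_tsc = TRUE,
                              include_case = TRUE, input_bias = TRUE))
#> [1] 2214475
build_case_grid()
#> case_grid: 16 training x 45 validation cases
```

A command-line surface is available via `run_command()` (or
`inst/cli/tubepinn.R`): subcommands `train`, `evaluate`, `sample-geometry`,
`count-params`, `reference`, `case-grid`; YAML configuration with the study
profile in `inst/config/paper_2d.yaml`.

## Scope and limitations

Straight, symmetric 2D channels with a single Gaussian narrowing at steady
state; laminar incompressible flow without body forces. CFD ground-truth
generation is out of scope — verification is against exact analytic
solutions (and optionally imported reference point clouds, CSV or legacy
ASCII VTK). Full-scale multi-case error tables require GPU-scale training
of ~2.2M-parameter networks and an external CFD reference, and are not
desk-reproducible here; the methods vignette
(`vignettes/multicase-pinn.Rmd`) details what the CPU-scale experiments do
and do not demonstrate.
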