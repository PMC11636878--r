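---
title: "Multi-case PINNs for stenotic tube flows: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-case PINNs for stenotic tube flows: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubepinn)
```

## The problem and the model

`tubepinn` builds surrogate solvers for steady incompressible flow in a
family of 2D channels with a Gaussian narrowing,

$$R(x) = R_0 - A\,e^{-(x-\mu)^2/(2\sigma^2)},$$

with $R_0 = 0.05$ m, $\mu = 0.5$ m, and case parameters
$\lambda = (A, \sigma)$ spanning $A \in [0.015, 0.035]$ m and
$\sigma \in [0.10, 0.18]$ m. The flow obeys continuity and steady
Navier–Stokes without body forces; boundary conditions are no-slip walls, a
parabolic inlet profile with $u_{\max} = 0.00925$ m/s, and zero outlet
pressure. A neural field $(u, v, p) = f(x, y; \lambda)$ is trained by
minimizing PDE residuals and boundary mismatches at sampled collocation
points — no labelled flow data enter the optimization.

**Viscosity.** The package default is $\nu = 1.85\times10^{-6}$ m²/s
(water-like). With the stated $u_{\max}$ and $R_0$ this gives an inlet
Reynolds number $u_{\max}\cdot 2R_0/\nu = 500$; the value is configurable
(`fluid_properties()`). Note that no single convention (local vs inlet
scale, mean vs peak velocity) maps these constants onto a Reynolds range of
375–450, so the package reports the convention it uses rather than a range.

**Channel length.** The axial extent is nowhere pinned down by the geometry
formula itself; with the narrowing centred at $x = 0.5$ m and the
centerline coordinate spanning $(-1, 1)$, the natural domain is
$x \in [0, 1]$ m. `length = 1` m is the default and is configurable.

**Coordinate convention.** $y = 0$ is the centerline and the walls are the
symmetric curves $y = \pm R(x)$, sampled separately (`wall_top`,
`wall_bottom`) but pooled into a single no-slip loss term.

## Unit normalization

All loss terms are made dimensionless with reference units
$V_{kg} = 1$ kg, $V_m = 0.1$ m (the inlet diameter $2R_0$) and
$V_s = 10.811$ s, chosen so that $V_m/V_s = u_{\max}$ to four significant
figures. Continuity residuals (units s⁻¹) are divided by $V_s^{-1}$,
momentum residuals by $V_m V_s^{-2}$, velocities by $V_m V_s^{-1}$ and
pressures by $V_{kg} V_m^{-1} V_s^{-2}$, squared, and averaged per term
with each boundary term using its own point count. With weights
$\omega_{physics} = \omega_{bc} = 1$ (the defaults) all terms are
comparable at O(1).

Internally the network predicts the *normalized* variables and the
interface rescales to SI; likewise the coordinate inputs are mapped to
$x_n = 2x/L - 1$ and $y_n = y/R_0$ and the case inputs to their ranges.
This is an implementation choice (it keeps activations and gradients
O(1)), not a change of model: all public inputs and outputs are SI.

**Inlet half-width.** The parabolic target uses $R_{inlet} = R_0$. The
narrowing amplitude at the inlet is $A\,e^{-\mu^2/(2\sigma^2)} \le
10^{-3} A$ over the trained $\sigma$ range, i.e. below any loss resolution;
treating $R_{inlet}$ as case-independent also makes the case-derivative of
the inlet target identically zero, so a case-independent field has exactly
zero gPINN loss.

## Architectures

All three multi-case architectures share a SiLU fully connected backbone
with an affine (activation-free) output layer:

* **mixed** — one network on `(x_n, y_n, TSC..., A_n, sigma_n)` (12 inputs
  with TSC);
* **hypernetwork** — `f_h(λ)` (hidden 32×5, then a feature layer, then a
  final affine map) emits every weight and bias of `f_m(x)`; only the
  `f_h` parameters are trainable;
* **modes** — `f_h(λ)` emits a $B \times 3$ modes array $\mathcal{M}$,
  `f_m(x)` emits $B$ mode weights $q$, and $\hat y_i = \sum_j q_j
  \mathcal{M}_{ji}$.

**Parameter counting conventions.** `count_parameters()` is exact and is
verified against brute-force enumeration of the allocated arrays. The
published single-case totals (445,443; 790,531; 3,153,923; 200,707) are
reproduced exactly with *no bias on the first hidden layer*; the
multi-case mixed totals (2,214,475; 808,575) with the first-layer bias
present and 12 inputs. `network_spec()` therefore exposes `input_bias`
explicitly. With the head layout above (hidden 32×5, feature width 10 or
3, final affine emitting the generated parameters, `B` = main width), the
published hypernetwork and modes totals are reproduced to within exactly
+32 parameters each (< 0.005%) — the remaining 32-vector appears to be an
artifact of the original implementation and is not modelled.
`paper_architectures()` instead chooses `B` as the largest integer keeping
the modes network within +0.1% of the mixed budget, which keeps all three
sizes within the ±0.1% comparability band:

```{r}
sapply(paper_architectures("large"), count_parameters)
```

**Initialization.** Glorot-normal weights with zero biases, seeded. For
the hypernetwork the final `f_h` layer gets near-zero weights while its
*bias* is set to a variance-scaled draw of the generated main-network
parameters: the composite then starts at a standard initialization with
weak case dependence. (Initializing the generated parameters themselves
near zero would make the composite untrainable — every path through `f_m`
would carry near-zero weights.)

## Tube-specific coordinates

Eight derived inputs: centerline distance $c = 2x/L - 1$, normalized width
$L_n = y/R(x)$, $d_{sq} = 1 - L_n^2$, $c^2$, $L_n^2$, $c\,d_{sq}$,
$c\,L_n$, $L_n d_{sq}$. $L_n$ uses *local* normalization (by $R(x)$, not
$R_0$), so $L_n = \pm 1$ exactly on the walls everywhere, including the
throat, and $d_{sq}$ vanishes exactly on the walls. For the straight
channel the exact solution is *linear* in these features
($u = u_{\max} d_{sq}$), which is precisely why TSC accelerate training:
the network no longer needs to synthesize squares and cross-products of
its inputs.

## The derivative engine

The PDE residuals need $u_x, u_y, p_x, \dots, u_{xx}, u_{yy}$; the gPINN
loss additionally needs $\partial/\partial\lambda$ of those residuals,
i.e. mixed third-order derivatives such as $u_{xx\lambda}$ — including the
dependence of the TSC features (and, for the hypernetwork, of the
generated weights) on $\lambda$. No R autodiff backend exists, so the
package implements a truncated-Taylor forward mode: every quantity carries
a declared set of derivative states (value; first derivatives in
$x, y, A, \sigma$; the second and third-order multi-indices the losses
require), propagated by precomputed Leibniz/chain-rule plans through the
geometry features and every network layer. SiLU derivatives up to fourth
order are evaluated in closed form (the fourth order appears only in the
reverse pass through third-order states). A matching hand-written reverse
pass accumulates exact gradients with respect to the trainable parameters,
including the route through hypernetwork-generated weights and their case
tangents.

Numerical policy: derivatives are exact up to floating point; the test
suite checks every path against central finite differences (step $10^{-4}$
on normalized inputs for spatial orders, $10^{-5}$–$10^{-6}$ for case
parameters) at relative tolerances of $10^{-4}$ (residuals) and $10^{-3}$
(case derivatives), on ≥100 random points across 5 seeds.

## gPINN derivative loss

The derivative loss is the mean of *squared* derivatives of the
unit-normalized residuals with respect to each case parameter, the
parameter being normalized by its trained range width (0.020 m for $A$,
0.08 m for $\sigma$), summed over both parameters; the boundary part is
evaluated on all boundary regions (walls, inlet, outlet), with wall points
following the wall ($y = \pm R(x;\lambda)$) under case differentiation. A
raw signed mean of derivatives is not a loss (it could be negative and
cancel); squaring follows the gradient-enhanced PINN literature. The
two-phase schedule (`train_gpinn_phase()`) trains with the plain loss
first and then resumes with the derivative term active; activation is
visible in the trace through the `phase` marker, and at fixed parameters
adding the nonnegative term can only raise the total — the test suite
asserts exactly that, rather than any quantitative spike height.

## Training

Each Adam iteration samples a fixed per-region schedule — by default 160
inlet + 160 outlet + 160 per wall + 3200 interior = 3840 points — split
evenly across the training cases (remainder round-robin). Interior points
are drawn from a per-case pre-generated pool of `pool_factor` (default
1000) times the per-iteration interior quota, regenerated every
`iterations_per_epoch` (default 1000) iterations; with the defaults one
epoch therefore consumes 3.84 million spatial points. Adam uses lr
$10^{-3}$ with cosine decay to $10^{-5}$ and betas (0.9, 0.999) — the
optimizer hyperparameters are not pinned by the study conditions and are
configurable. Runs are reproducible bit-for-bit given the config seed
(sampling, initialization and updates share one seeded stream; traces
differ only in wall-clock columns). A divergence guard aborts if the total
loss exceeds $10^6\times$ its initial value for 100 consecutive steps.

The 16 training cases are the product of 4 arithmetically spaced $A$ and 4
logarithmically spaced $\sigma$ values, endpoints included; the 45
validation cases interleave 9 arithmetically spaced $A$ and 5 log-spaced
$\sigma$ values at half-step offsets, guaranteeing disjointness. The exact
validation coordinates are not published; the half-step layout is this
package's choice and is configurable. Note that an endpoint-inclusive
geometric grid of even length cannot contain the geometric midpoint
$\sqrt{0.10 \times 0.18} = 0.1342$; that midpoint is the *single-case*
benchmark $\sigma$ (`paper_single_case()`), not a training case.

## Verification strategy and problem sizes

CFD ground truth is out of scope, so correctness rests on analytic
references and property tests:

* the straight channel ($A = 0$) has the exact solution
  $u = u_{\max}(1 - y^2/R_0^2)$, $v = 0$,
  $p = 2\rho\nu u_{\max}(L - x)/R_0^2$; pushed through the full loss
  machinery it yields physics + BC losses at rounding level ($\sim
  10^{-33}$), and perturbing it by a smooth $O(\varepsilon)$ field raises
  the losses as $O(\varepsilon^2)$ (log–log slope 2);
* a zero model reproduces the closed-form inlet deficit
  $\tfrac{8}{15}u_{\max}^2/(V_m V_s^{-1})^2 \approx 8/15$;
* the hypernetwork at frozen $\lambda$ is *identical* (to $10^{-12}$) to a
  plain network carrying the emitted parameters, and the modes output is
  exactly linear in $\mathcal{M}$;
* wall shear stress uses $\mu\,|E\,\hat n|$ with
  $E = (\nabla v + \nabla v^\top)/2$ and analytic wall normals
  $\hat n \propto (R'(x), \mp 1)$ — the difference from vertical normals
  matters at the narrowing shoulders. As defined, unidirectional shear
  gives $\mu u_{\max}/R_0 = 3.4225\times10^{-4}$ Pa on the straight
  channel wall, *half* the conventional Newtonian value
  $\tau = 2\mu E \hat n$; the convention flag
  (`wss_convention = "as_printed"` / `"conventional_2x"`) makes the
  factor explicit.

The desk-scale training experiment uses a 3×64 mixed network (9219
parameters) with TSC on the straight channel, batches of 384 points
(32/32/32/32/256), pool factor 100, and convergence checks every 200
iterations against the analytic field on a 50×50 grid; it reaches < 5%
relative L2 error in $u$ in roughly 2000–2500 iterations, while the same
budget without TSC does not get there in the same number of iterations.
These sizes are the package's verification choices — large enough to show
the TSC effect, small enough to run routinely on one CPU.

**What passing these tests does and does not show.** The synthetic
conditions exercise exact derivatives, loss normalization, optimization
and the TSC advantage on a geometry with a known solution. They do not
certify accuracy on narrowed cases ($A > 0$), which in the original study
is measured against external CFD at GPU scale (~2.2M-parameter networks,
hours of training); those error tables are explicitly out of scope here.
Imported reference point clouds (CSV/VTK, `import_reference()`) allow the
same error pipeline to be run against an external solver when one is
available; interpolation is nearest-neighbour or inverse-distance
(recorded in the report), as no scattered-interpolation dependency is
assumed.

## Degenerate inputs, tolerances, tie-breaks

* $A = 0$ reduces every geometry operation to the straight channel; such
  cases are valid and unflagged. Out-of-range cases are accepted with a
  warning; $A \ge R_0$ (channel closure) is an error.
* On-boundary classification uses an absolute tolerance of $10^{-12}$ m
  (the geometry is analytic, double precision).
* `compute_tsc()` rejects points with $|y| > R(x)(1 + 10^{-9})$.
* Checkpoints (RDS with schema tag + md5) restore parameters bit-exactly;
  corrupted files raise explicit integrity errors.
* `relative_l2()` refuses an identically zero reference rather than
  returning an infinity.

## Known limitations

* CPU-scale only: the published multi-case error tables and wall-clock
  convergence comparisons require GPU-scale training and are not
  reproduced.
* Single symmetric Gaussian narrowing in 2D; no curvature, asymmetry,
  multiple stenoses, 3D, or unsteady terms.
* The hypernetwork is memory- and compute-heavy by construction (its
  reverse pass threads through every generated weight); at desk scale it
  is exercised with small widths.
* The gPINN boundary term's region set (all boundaries vs walls only) is
  not uniquely determined by the study description; all boundary regions
  are included, and the choice is localized in `gpinn_loss()`.
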