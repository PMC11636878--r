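# ---------------------------------------------------------------------------
# Fluid properties, unit normalization and the shared model context.
# ---------------------------------------------------------------------------

#' Fluid properties
#'
#' Water-like defaults: density 1000 kg/m^3, kinematic viscosity
#' 1.85e-6 m^2/s (giving an inlet Reynolds number u_max * 2 R0 / nu = 500).
#'
#' @param rho density in kg/m^3.
#' @param nu kinematic viscosity in m^2/s.
#' @return list with `rho`, `nu` and the dynamic viscosity `mu_dyn = rho*nu`
#'   in Pa s.
#' @export
fluid_properties <- function(rho = 1000, nu = 1.85e-6) {
  stopifnot(rho > 0, nu > 0)
  list(rho = rho, nu = nu, mu_dyn = rho * nu)
}

#' Unit-normalization constants
#'
#' The loss terms are made dimensionless with reference units of 1 kg,
#' 0.1 m (the inlet diameter 2 R0) and 10.811 s, chosen so that
#' V_m / V_s equals the peak inlet velocity u_max = 0.00925 m/s to four
#' significant figures.
#'
#' @param V_kg,V_m,V_s reference mass (kg), length (m) and time (s).
#' @return list with the three constants and the derived velocity and
#'   pressure scales `V_u = V_m/V_s`, `V_p = V_kg/(V_m V_s^2)`.
#' @export
normalization_constants <- function(V_kg = 1, V_m = 0.1, V_s = 10.811) {
  stopifnot(V_kg > 0, V_m > 0, V_s > 0)
  list(V_kg = V_kg, V_m = V_m, V_s = V_s,
       V_u = V_m / V_s, V_p = V_kg / (V_m * V_s^2))
}

#' Shared model context
#'
#' Bundles everything a model needs besides its weights: base geometry
#' constants, the case-parameter ranges (used to normalize the lambda
#' inputs), inlet velocity, fluid properties and normalization constants.
#'
#' @param R0 reference half-width (m).
#' @param x_center narrowing centre (m).
#' @param length channel length (m).
#' @param A_range,sigma_range trained case-parameter ranges (m).
#' @param u_max peak inlet velocity (m/s).
#' @param fluid a [fluid_properties()] list.
#' @param norms a [normalization_constants()] list.
#' @param wss_convention `"as_printed"` (symmetric gradient tensor without
#'   the conventional factor 2) or `"conventional_2x"`.
#' @return object of class `pinn_context`.
#' @export
pinn_context <- function(R0 = 0.05, x_center = 0.5, length = 1.0,
                         A_range = c(0.015, 0.035),
                         sigma_range = c(0.10, 0.18),
                         u_max = 0.00925,
                         fluid = fluid_properties(),
                         norms = normalization_constants(),
                         wss_convention = c("as_printed", "conventional_2x")) {
  wss_convention <- match.arg(wss_convention)
  structure(list(R0 = R0, x_center = x_center, length = length,
                 A_range = A_range, sigma_range = sigma_range,
                 u_max = u_max, fluid = fluid, norms = norms,
                 wss_convention = wss_convention),
            class = "pinn_context")
}

# geometry of a given case under this context
ctx_geometry <- function(ctx, case) {
  if (!inherits(case, "case_parameters")) {
    case <- suppressWarnings(case_parameters(case[[1]], case[[2]]))
  }
  channel_geometry(case, R0 = ctx$R0, x_center = ctx$x_center,
                   length = ctx$length)
}
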