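# ---------------------------------------------------------------------------
# Parameterized stenotic channel geometry.
#
# The channel is symmetric about the centerline y = 0 with half-width
#   R(x) = R0 - A * exp(-(x - x_center)^2 / (2 sigma^2)),
# a Gaussian narrowing of amplitude A (m) and length scale sigma (m).
# ---------------------------------------------------------------------------

#' Case parameters of the narrowing family
#'
#' One geometry case lambda = (A, sigma).  The trained ranges are
#' A in \[0.015, 0.035\] m and sigma in \[0.10, 0.18\] m; values outside are
#' accepted but flagged with a warning (A = 0 is the straight-channel
#' degenerate case used for analytic verification).
#'
#' @param A narrowing amplitude in metres (>= 0).
#' @param sigma narrowing length scale in metres (> 0).
#' @return object of class `case_parameters`.
#' @export
#' @examples
#' case_parameters(0.025, 0.134)
#' case_parameters(0, 0.134)  # straight channel
case_parameters <- function(A, sigma) {
  stopifnot(is.numeric(A), is.numeric(sigma), length(A) == 1L, length(sigma) == 1L)
  if (A < 0) stop("A must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  in_range <- (A == 0) || (A >= 0.015 - 1e-12 && A <= 0.035 + 1e-12 &&
                           sigma >= 0.10 - 1e-12 && sigma <= 0.18 + 1e-12)
  if (!in_range) {
    warning("case (A = ", A, ", sigma = ", sigma,
            ") lies outside the trained range A in [0.015, 0.035], sigma in [0.10, 0.18]")
  }
  structure(list(A = A, sigma = sigma, in_range = in_range),
            class = "case_parameters")
}

#' Channel geometry
#'
#' @param case a [case_parameters()] object.
#' @param R0 reference half-width in metres (default 0.05).
#' @param x_center centre of the Gaussian narrowing in metres (default 0.5).
#' @param length axial channel length in metres (default 1.0; the domain is
#'   x in \[0, length\]).
#' @return object of class `channel_geometry`.
#' @export
channel_geometry <- function(case = case_parameters(0, 0.134),
                             R0 = 0.05, x_center = 0.5, length = 1.0) {
  stopifnot(R0 > 0, length > 0)
  if (inherits(case, "channel_geometry")) stop("pass case_parameters, not a geometry")
  if (!inherits(case, "case_parameters")) case <- case_parameters(case[[1]], case[[2]])
  if (R0 - case$A <= 0) stop("narrowing amplitude closes the channel: A >= R0")
  structure(list(case = case, R0 = R0, x_center = x_center, length = length),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("2D stenotic channel: R0 = %g m, length = %g m, narrowing A = %g m, sigma = %g m at x = %g m\n",
              x$R0, x$length, x$case$A, x$case$sigma, x$x_center))
  invisible(x)
}

#' Channel half-width profile
#'
#' Evaluates R(x) = R0 - A exp(-(x - x_center)^2 / (2 sigma^2)); vectorized
#' over `x`.
#'
#' @param x axial positions in metres.
#' @param geom a [channel_geometry()].
#' @return half-widths in metres.
#' @export
#' @examples
#' g <- channel_geometry(case_parameters(0.035, 0.12))
#' radius_profile(0.5, g)  # 0.05 - 0.035 = 0.015 at the throat
radius_profile <- function(x, geom) {
  geom$R0 - geom$case$A * exp(-(x - geom$x_center)^2 / (2 * geom$case$sigma^2))
}

# d/dx of the half-width (used for analytic wall normals)
radius_profile_dx <- function(x, geom) {
  A <- geom$case$A; s <- geom$case$sigma; mu <- geom$x_center
  A * (x - mu) / s^2 * exp(-(x - mu)^2 / (2 * s^2))
}

#' Unit inward wall normals
#'
#' Analytic unit normals of the wall curves y = +/- R(x), oriented into the
#' fluid; proportional to (-dR/dx, -1) on the top wall and (-(-dR/dx), +1)
#' on the bottom wall before normalization.
#'
#' @param x axial positions in metres.
#' @param side `"top"` or `"bottom"`.
#' @param geom a [channel_geometry()].
#' @return a 2-column matrix of unit normal components (nx, ny).
#' @export
wall_normals <- function(x, side = c("top", "bottom"), geom) {
  side <- match.arg(side)
  dR <- radius_profile_dx(x, geom)
  s <- if (side == "top") 1 else -1
  # wall curve y = s * R(x) has tangent (1, s * dR/dx); the inward normal
  # is (dR/dx, -s) / |.| for both walls
  nx <- dR; ny <- rep(-s, length(x))
  nrm <- sqrt(nx^2 + ny^2)
  cbind(nx = nx / nrm, ny = ny / nrm)
}

#' Tube-specific coordinates (TSC)
#'
#' Computes the eight tube-specific coordinate inputs at points (x, y):
#' centerline distance `c = 2x/length - 1` (in (-1, 1)), normalized width
#' `L_n = y / R(x)` (in (-1, 1), +/-1 exactly on the walls), the
#' wall-distance surrogate `d_sq = 1 - L_n^2`, and the products
#' `c_sq = c^2`, `L_n_sq = L_n^2`, `c_dsq = c d_sq`, `c_Ln = c L_n`,
#' `Ln_dsq = L_n d_sq`.
#'
#' @param x,y point coordinates in metres (vectorized, recycled).
#' @param geom a [channel_geometry()].
#' @param tol relative tolerance for the inside-channel check.
#' @return data.frame with columns `c, L_n, d_sq, c_sq, L_n_sq, c_dsq, c_Ln,
#'   Ln_dsq`.
#' @export
#' @examples
#' g <- channel_geometry(case_parameters(0, 0.134))
#' compute_tsc(0, 0, g)  # inlet centerline: c = -1, L_n = 0, d_sq = 1
compute_tsc <- function(x, y, geom, tol = 1e-9) {
  R <- radius_profile(x, geom)
  if (any(abs(y) > R * (1 + tol))) {
    bad <- which(abs(y) > R * (1 + tol))[1L]
    stop(sprintf("point (%.6g, %.6g) lies outside the channel (|y| > R(x) = %.6g)",
                 x[bad], y[bad], R[bad]))
  }
  cc <- 2 * x / geom$length - 1
  Ln <- y / R
  dsq <- 1 - Ln^2
  data.frame(c = cc, L_n = Ln, d_sq = dsq, c_sq = cc^2, L_n_sq = Ln^2,
             c_dsq = cc * dsq, c_Ln = cc * Ln, Ln_dsq = Ln * dsq)
}

#' Parabolic inlet velocity profile
#'
#' u(y) = u_max (1 - y^2 / R_inlet^2); the transverse component v is zero.
#'
#' @param y transverse positions in metres, |y| <= R_inlet.
#' @param u_max peak inlet velocity in m/s (default 0.00925).
#' @param R_inlet inlet half-width in metres (default 0.05).
#' @return axial velocities in m/s.
#' @export
inlet_profile <- function(y, u_max = 0.00925, R_inlet = 0.05) {
  u_max * (1 - y^2 / R_inlet^2)
}

#' Wall polylines for plotting
#'
#' @param geom a [channel_geometry()].
#' @param n number of samples along the channel.
#' @return data.frame with columns `x`, `y_top`, `y_bottom`.
#' @export
wall_polyline <- function(geom, n = 200L) {
  x <- seq(0, geom$length, length.out = n)
  R <- radius_profile(x, geom)
  data.frame(x = x, y_top = R, y_bottom = -R)
}
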