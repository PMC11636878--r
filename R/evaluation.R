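# ---------------------------------------------------------------------------
# Error analysis: relative L2 errors, wall shear stress, reference-field
# import and case-grid error maps.
# ---------------------------------------------------------------------------

#' Relative L2 error (percent)
#'
#' 100 * ||pred - ref||_2 / ||ref||_2.
#'
#' @param pred,ref numeric vectors of equal length (>= 1).
#' @return percentage error.
#' @export
#' @examples
#' relative_l2(c(1, 2), c(1, 1))  # 100 / sqrt(2) = 70.71%
relative_l2 <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(ref) >= 1L)
  denom <- sqrt(sum(ref^2))
  if (denom == 0) stop("reference field is identically zero: relative L2 undefined")
  100 * sqrt(sum((pred - ref)^2)) / denom
}

#' Wall shear stress magnitude from velocity-gradient tensors
#'
#' Computes mu * |E n| with E = (grad v + grad v^T) / 2 the symmetric
#' velocity-gradient tensor and n the unit wall normal.  The default
#' convention follows the definition used for the reference results (the
#' symmetric tensor without the conventional factor 2, which for
#' unidirectional shear gives half the textbook Newtonian wall shear
#' stress); `convention = "conventional_2x"` applies tau = 2 mu E n.
#'
#' @param grad matrix with columns `ux, uy, vx, vy` (velocity gradients at
#'   wall points, 1/s).
#' @param normals 2-column matrix of unit normals.
#' @param mu_dyn dynamic viscosity (Pa s).
#' @param convention `"as_printed"` or `"conventional_2x"`.
#' @return WSS magnitudes in Pa.
#' @export
wall_shear_stress <- function(grad, normals, mu_dyn,
                              convention = c("as_printed", "conventional_2x")) {
  convention <- match.arg(convention)
  grad <- as.matrix(grad); normals <- as.matrix(normals)
  stopifnot(ncol(grad) == 4L, ncol(normals) == 2L,
            nrow(grad) == nrow(normals))
  nrm <- sqrt(rowSums(normals^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("wall normals must be unit vectors")
  ux <- grad[, 1L]; uy <- grad[, 2L]; vx <- grad[, 3L]; vy <- grad[, 4L]
  exy <- (uy + vx) / 2
  tx <- ux * normals[, 1L] + exy * normals[, 2L]
  ty <- exy * normals[, 1L] + vy * normals[, 2L]
  fac <- if (convention == "conventional_2x") 2 else 1
  fac * mu_dyn * sqrt(tx^2 + ty^2)
}

#' Wall shear stress of a flow field along a channel wall
#'
#' Evaluates the exact velocity gradients of the field at wall points and
#' applies [wall_shear_stress()] with analytic wall normals.
#'
#' @param field a `pinn_model` or [flow_field()].
#' @param x axial positions (m).
#' @param side `"top"` or `"bottom"`.
#' @param case case parameters.
#' @param convention passed to [wall_shear_stress()]; default taken from the
#'   field's context.
#' @return data.frame `x`, `wss` (Pa).
#' @export
model_wall_shear_stress <- function(field, x, side = c("top", "bottom"),
                                    case = case_parameters(0, 0.134),
                                    convention = NULL) {
  side <- match.arg(side)
  ctx <- field$ctx
  if (is.null(convention)) convention <- ctx$wss_convention
  geom <- ctx_geometry(ctx, case)
  s <- if (side == "top") 1 else -1
  y <- s * radius_profile(x, geom)
  ev <- flow_eval(field, x, y, case, ss_grad_xy())
  gx <- ev$states[[ss_state_id(ss_grad_xy(), "x")]]
  gy <- ev$states[[ss_state_id(ss_grad_xy(), "y")]]
  grad <- cbind(ux = gx[, 1L], uy = gy[, 1L], vx = gx[, 2L], vy = gy[, 2L])
  nrm <- wall_normals(x, side, geom)
  data.frame(x = x,
             wss = wall_shear_stress(grad, nrm, ctx$fluid$mu_dyn, convention))
}

# ---------------------------------------------------------------------------
# Reference fields on point clouds
# ---------------------------------------------------------------------------

#' Import a reference flow field from CSV or legacy-ASCII VTK
#'
#' CSV files need a header with columns `x, y, u, v, p`.  VTK support covers
#' legacy ASCII files with `POINTS` and point-data arrays (`SCALARS u/v/p`
#' or a `VECTORS` velocity plus `SCALARS p`).
#'
#' @param path file path.
#' @param format `"csv"` or `"vtk"` (default inferred from the extension).
#' @return data.frame `x, y, u, v, p` with class `reference_field`.
#' @export
import_reference <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.vtk$", path, ignore.case = TRUE)) "vtk" else "csv"
  }
  format <- match.arg(format, c("csv", "vtk"))
  df <- if (format == "csv") {
    d <- utils::read.csv(path)
    need <- c("x", "y", "u", "v", "p")
    if (!all(need %in% names(d))) {
      stop("reference CSV must have columns x, y, u, v, p; missing: ",
           paste(setdiff(need, names(d)), collapse = ", "))
    }
    d[, need]
  } else {
    read_vtk_points(path)
  }
  if (!nrow(df)) stop("empty reference field")
  if (any(!is.finite(as.matrix(df)))) stop("non-finite values in reference field")
  class(df) <- c("reference_field", class(df))
  df
}

# minimal legacy ASCII VTK reader (POINTS + point data u, v, p)
read_vtk_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nums <- function(from, count) {
    vals <- numeric(0); i <- from
    while (length(vals) < count && i <= length(lines)) {
      vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      i <- i + 1L
    }
    list(vals = vals[seq_len(count)], nxt = i)
  }
  ip <- grep("^POINTS", lines)
  if (!length(ip)) stop("VTK file lacks a POINTS section")
  npts <- as.integer(strsplit(trimws(lines[ip[1]]), "\\s+")[[1]][2])
  pts <- nums(ip[1] + 1L, 3L * npts)
  xyz <- matrix(pts$vals, ncol = 3L, byrow = TRUE)
  if (any(abs(xyz[, 3L]) > 1e-12)) stop("VTK point cloud is not 2D (z != 0)")
  fields <- list()
  for (i in grep("^SCALARS", lines)) {
    nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    start <- i + if (grepl("^LOOKUP_TABLE", lines[i + 1L])) 2L else 1L
    fields[[nm]] <- nums(start, npts)$vals
  }
  for (i in grep("^VECTORS", lines)) {
    vec <- nums(i + 1L, 3L * npts)$vals
    m <- matrix(vec, ncol = 3L, byrow = TRUE)
    fields$u <- m[, 1L]; fields$v <- m[, 2L]
  }
  need <- c("u", "v", "p")
  if (!all(need %in% names(fields))) {
    stop("VTK point data must provide u, v, p; missing: ",
         paste(setdiff(need, names(fields)), collapse = ", "))
  }
  data.frame(x = xyz[, 1L], y = xyz[, 2L],
             u = fields$u, v = fields$v, p = fields$p)
}

#' Interpolate a reference field onto evaluation points
#'
#' Nearest-point (default) or inverse-distance-weighted interpolation of a
#' scattered reference field; when every evaluation point coincides with a
#' reference point no interpolation is applied.  The method used is recorded
#' in the `interpolation` attribute.
#'
#' @param ref a [import_reference()] data.frame (or any `x,y,u,v,p` frame).
#' @param points data.frame with `x`, `y`.
#' @param method `"nearest"` or `"idw"`.
#' @param k neighbours for `"idw"`.
#' @return data.frame `x, y, u, v, p` at the requested points.
#' @export
interp_reference <- function(ref, points, method = c("nearest", "idw"), k = 4L) {
  method <- match.arg(method)
  n <- nrow(points)
  out <- data.frame(x = points$x, y = points$y,
                    u = numeric(n), v = numeric(n), p = numeric(n))
  # length scales differ strongly between axes; normalize by spans
  sx <- max(diff(range(ref$x)), .Machine$double.eps)
  sy <- max(diff(range(ref$y)), .Machine$double.eps)
  exact <- TRUE
  for (i in seq_len(n)) {
    d2 <- ((ref$x - points$x[i]) / sx)^2 + ((ref$y - points$y[i]) / sy)^2
    if (method == "nearest") {
      j <- which.min(d2)
      if (d2[j] > 0) exact <- FALSE
      out$u[i] <- ref$u[j]; out$v[i] <- ref$v[j]; out$p[i] <- ref$p[j]
    } else {
      ord <- order(d2)[seq_len(min(k, nrow(ref)))]
      if (d2[ord[1]] == 0) {
        j <- ord[1]
        out$u[i] <- ref$u[j]; out$v[i] <- ref$v[j]; out$p[i] <- ref$p[j]
      } else {
        exact <- FALSE
        w <- 1 / d2[ord]
        w <- w / sum(w)
        out$u[i] <- sum(w * ref$u[ord])
        out$v[i] <- sum(w * ref$v[ord])
        out$p[i] <- sum(w * ref$p[ord])
      }
    }
  }
  attr(out, "interpolation") <- if (exact) "none (exact point match)" else method
  out
}

#' Error report for one case
#'
#' Relative L2 errors of u, v, p on interior evaluation points and of the
#' wall shear stress magnitude along both walls.
#'
#' @param model a `pinn_model` (or `flow_field`).
#' @param reference a `flow_field`, `reference_field` data.frame, or function
#'   `(points, case) -> data.frame(u, v, p)`.
#' @param case case parameters.
#' @param n number of random interior evaluation points.
#' @param n_wall wall points per side for the WSS error (0 to skip).
#' @param seed RNG seed for the evaluation points.
#' @return object of class `error_report`: list with `epsilon_u`,
#'   `epsilon_v`, `epsilon_p`, `epsilon_wss_mag` (percent), `N`, `case`.
#' @export
error_report <- function(model, reference, case, n = 10000L, n_wall = 200L,
                         seed = 1L) {
  ctx <- model$ctx
  geom <- ctx_geometry(ctx, case)
  pts <- collocation_pool(geom, n, seed = seed)
  pred <- predict_flow(model, pts$x, pts$y, case)
  ref <- reference_values(reference, pts, case)
  eps_wss <- NA_real_
  if (n_wall > 0 && (inherits(reference, "flow_field") ||
                     inherits(reference, "pinn_model"))) {
    xw <- seq(0, geom$length, length.out = n_wall)
    wss_p <- rbind(model_wall_shear_stress(model, xw, "top", case),
                   model_wall_shear_stress(model, xw, "bottom", case))
    wss_r <- rbind(model_wall_shear_stress(reference, xw, "top", case),
                   model_wall_shear_stress(reference, xw, "bottom", case))
    eps_wss <- relative_l2(wss_p$wss, wss_r$wss)
  }
  structure(list(epsilon_u = relative_l2(pred$u, ref$u),
                 epsilon_v = if (all(ref$v == 0)) NA_real_ else relative_l2(pred$v, ref$v),
                 epsilon_p = relative_l2(pred$p, ref$p),
                 epsilon_wss_mag = eps_wss,
                 N = n, case = case),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report (A = %g, sigma = %g, N = %d): eps_u = %.3f%%, eps_v = %s, eps_p = %.3f%%, eps_WSS = %s\n",
              x$case$A, x$case$sigma, x$N, x$epsilon_u,
              if (is.na(x$epsilon_v)) "NA" else sprintf("%.3f%%", x$epsilon_v),
              x$epsilon_p,
              if (is.na(x$epsilon_wss_mag)) "NA" else sprintf("%.3f%%", x$epsilon_wss_mag)))
  invisible(x)
}

reference_values <- function(reference, pts, case) {
  if (inherits(reference, "flow_field") || inherits(reference, "pinn_model")) {
    sample_flow_field(reference, pts, case)
  } else if (is.function(reference)) {
    reference(pts, case)
  } else if (is.data.frame(reference)) {
    interp_reference(reference, pts)
  } else stop("unsupported reference type")
}

#' Per-case error table over a case grid
#'
#' Evaluates [error_report()] for each case of a grid for which a reference
#' is available; emits a contour-ready table `(A, sigma, eps_u, eps_v,
#' eps_p, eps_wss)`.  Cases for which `reference_for` returns `NULL` are
#' reported as skipped.
#'
#' @param model a `pinn_model`.
#' @param cases data.frame of cases (`A`, `sigma`), e.g. a [build_case_grid()]
#'   component.
#' @param reference_for function `case_parameters -> reference` (or `NULL`
#'   to skip the case).
#' @param n,n_wall,seed evaluation sampling controls (see [error_report()]).
#' @return data.frame, one row per case, with a `skipped` logical column.
#' @export
case_grid_errors <- function(model, cases, reference_for,
                             n = 10000L, n_wall = 200L, seed = 1L) {
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    cp <- suppressWarnings(case_parameters(cases$A[i], cases$sigma[i]))
    ref <- reference_for(cp)
    if (is.null(ref)) {
      return(data.frame(A = cp$A, sigma = cp$sigma, eps_u = NA_real_,
                        eps_v = NA_real_, eps_p = NA_real_, eps_wss = NA_real_,
                        N = 0L, skipped = TRUE))
    }
    er <- error_report(model, ref, cp, n = n, n_wall = n_wall, seed = seed + i)
    data.frame(A = cp$A, sigma = cp$sigma, eps_u = er$epsilon_u,
               eps_v = er$epsilon_v, eps_p = er$epsilon_p,
               eps_wss = er$epsilon_wss_mag, N = er$N, skipped = FALSE)
  })
  do.call(rbind, rows)
}
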