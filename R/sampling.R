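# ---------------------------------------------------------------------------
# Collocation sampling and the multi-case training/validation grids.
# ---------------------------------------------------------------------------

REGIONS <- c("inlet", "outlet", "wall_top", "wall_bottom", "interior")

#' Default per-iteration collocation counts
#'
#' The training schedule places 160 points on each of the inlet, outlet and
#' the two walls and 3200 in the interior, i.e. 3840 points per iteration.
#'
#' @return named integer vector over regions.
#' @export
default_batch_counts <- function() {
  c(inlet = 160L, outlet = 160L, wall_top = 160L, wall_bottom = 160L,
    interior = 3200L)
}

#' Sample collocation points in a stenotic channel
#'
#' Interior points are uniform in x and then uniform in y in (-R(x), R(x));
#' boundary points are uniform along their curve.  Wall points sit exactly on
#' y = +/- R(x).  Sampling is deterministic given `seed`.
#'
#' @param geom a [channel_geometry()].
#' @param counts named integer vector over
#'   `inlet, outlet, wall_top, wall_bottom, interior`
#'   (default [default_batch_counts()]); unnamed vectors are taken in that
#'   order.
#' @param seed integer RNG seed.
#' @param case_index integer tag recorded for every point (multi-case
#'   bookkeeping).
#' @return object of class `collocation_set`: a list with `points` (a
#'   data.frame with coordinates, region, case parameters and the eight TSC
#'   columns) and `geom`.
#' @export
#' @examples
#' g <- channel_geometry(case_parameters(0.025, 0.134))
#' cs <- sample_collocation(g, seed = 1)
#' table(cs$points$region)
sample_collocation <- function(geom, counts = default_batch_counts(),
                               seed = 1L, case_index = 1L) {
  if (is.null(names(counts))) names(counts) <- REGIONS
  stopifnot(all(names(counts) %in% REGIONS), all(counts >= 0))
  counts <- counts[REGIONS]
  counts[is.na(counts)] <- 0L
  names(counts) <- REGIONS
  rng <- local_rng(seed)
  piece <- function(region, n) {
    if (n == 0L) return(NULL)
    switch(region,
      inlet = {
        R0in <- radius_profile(0, geom)
        data.frame(x = rep(0, n), y = rng$runif(n, -R0in, R0in), region = region)
      },
      outlet = {
        RL <- radius_profile(geom$length, geom)
        data.frame(x = rep(geom$length, n), y = rng$runif(n, -RL, RL), region = region)
      },
      wall_top = {
        x <- rng$runif(n, 0, geom$length)
        data.frame(x = x, y = radius_profile(x, geom), region = region)
      },
      wall_bottom = {
        x <- rng$runif(n, 0, geom$length)
        data.frame(x = x, y = -radius_profile(x, geom), region = region)
      },
      interior = {
        x <- rng$runif(n, 0, geom$length)
        R <- radius_profile(x, geom)
        data.frame(x = x, y = rng$runif(n, -R, R), region = region)
      })
  }
  pts <- do.call(rbind, lapply(REGIONS, function(r) piece(r, counts[[r]])))
  if (is.null(pts)) {
    pts <- data.frame(x = numeric(), y = numeric(), region = character())
  }
  tsc <- compute_tsc(pts$x, pts$y, geom, tol = 1e-9)
  pts <- cbind(pts,
               case_A = geom$case$A, case_sigma = geom$case$sigma,
               case_index = case_index, tsc)
  structure(list(points = pts, geom = geom), class = "collocation_set")
}

#' @export
print.collocation_set <- function(x, ...) {
  tab <- table(factor(x$points$region, levels = REGIONS))
  cat("collocation_set:", nrow(x$points), "points (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read a collocation set as columnar CSV
#'
#' Columns: `x, y, region, case_A, case_sigma, c, L_n, d_sq, c_sq, L_n_sq,
#' c_dsq, c_Ln, Ln_dsq`.
#'
#' @param cs a `collocation_set`.
#' @param path file path.
#' @return `read_collocation_csv` returns a data.frame.
#' @export
write_collocation_csv <- function(cs, path) {
  cols <- c("x", "y", "region", "case_A", "case_sigma",
            "c", "L_n", "d_sq", "c_sq", "L_n_sq", "c_dsq", "c_Ln", "Ln_dsq")
  utils::write.csv(cs$points[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_collocation_csv
#' @export
read_collocation_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# RNG helper: isolated, seed-stable stream that does not disturb the global
# RNG state of the caller.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  use <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(runif = use(stats::runif), rnorm = use(stats::rnorm),
       sample_int = use(function(n, size, replace = FALSE) sample.int(n, size, replace = replace)))
}

#' Training / validation case grid
#'
#' The 16 training cases are the Cartesian product of `n_A` arithmetically
#' spaced amplitudes over `A_range` and `n_sigma` logarithmically spaced
#' length scales over `sigma_range`, endpoints included.  The default
#' validation layout interleaves 9 arithmetically spaced A values and 5
#' logarithmically spaced sigma values strictly between the training
#' positions (offset half-steps on a refined grid), giving 45 cases disjoint
#' from the training set.
#'
#' @param n_A,n_sigma number of training values per axis (>= 2).
#' @param A_range,sigma_range parameter ranges in metres.
#' @param validation_layout integer vector `c(n_A_val, n_sigma_val)`.
#' @return object of class `case_grid`: list with data.frames `training`
#'   (n_A * n_sigma rows) and `validation` (product of `validation_layout`
#'   rows), each with columns `A`, `sigma`.
#' @export
#' @examples
#' cg <- build_case_grid()
#' nrow(cg$training); nrow(cg$validation)
build_case_grid <- function(n_A = 4L, n_sigma = 4L,
                            A_range = c(0.015, 0.035),
                            sigma_range = c(0.10, 0.18),
                            validation_layout = c(9L, 5L)) {
  if (n_A < 2L || n_sigma < 2L) stop("n_A and n_sigma must be >= 2")
  A_tr <- seq(A_range[1], A_range[2], length.out = n_A)
  sig_tr <- exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = n_sigma))
  sig_tr[c(1L, n_sigma)] <- sigma_range  # endpoints exact despite exp/log rounding
  training <- expand.grid(A = A_tr, sigma = sig_tr, KEEP.OUT.ATTRS = FALSE)
  nAv <- validation_layout[1]; nSv <- validation_layout[2]
  # half-step offsets on a 2n-fold refinement keep validation off the
  # training positions while staying arithmetically / log spaced
  A_val <- A_range[1] + (2 * seq_len(nAv) - 1) / (2 * nAv) * diff(A_range)
  sig_val <- exp(log(sigma_range[1]) +
                 (2 * seq_len(nSv) - 1) / (2 * nSv) * diff(log(sigma_range)))
  validation <- expand.grid(A = A_val, sigma = sig_val, KEEP.OUT.ATTRS = FALSE)
  key <- function(df) paste(signif(df$A, 12), signif(df$sigma, 12))
  if (any(key(validation) %in% key(training))) {
    stop("validation layout collides with training cases")
  }
  structure(list(training = training, validation = validation),
            class = "case_grid")
}

#' @export
print.case_grid <- function(x, ...) {
  cat("case_grid:", nrow(x$training), "training x", nrow(x$validation),
      "validation cases\n")
  invisible(x)
}

#' The single-case benchmark geometry (A = 0.025, sigma = 0.134)
#'
#' The mid-range narrowing used for single-case experiments: A is the
#' arithmetic midpoint of the amplitude range and sigma the geometric
#' midpoint of the length-scale range (sqrt(0.10 * 0.18) = 0.13416).
#'
#' @return a [case_parameters()] object.
#' @export
paper_single_case <- function() {
  case_parameters(0.025, sqrt(0.10 * 0.18))
}

#' Pre-generated interior collocation pool
#'
#' Training batches draw interior points from a pool `pool_factor` times the
#' per-iteration interior count, regenerated each epoch.
#'
#' @param geom a [channel_geometry()].
#' @param n pool size (number of interior points).
#' @param seed integer RNG seed.
#' @return data.frame of interior points `x`, `y`.
#' @export
collocation_pool <- function(geom, n, seed = 1L) {
  rng <- local_rng(seed)
  x <- rng$runif(n, 0, geom$length)
  R <- radius_profile(x, geom)
  data.frame(x = x, y = rng$runif(n, -R, R))
}
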