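# ---------------------------------------------------------------------------
# Fully connected SiLU networks and the three multi-case architectures.
#
# kind = "mixed":        one FCNN on (coordinates [+ TSC], case parameters)
# kind = "hypernetwork": side FCNN f_h(lambda) emits every weight/bias of f_m
# kind = "modes":        f_h(lambda) emits a B x 3 modes array M, f_m(x)
#                        emits mode weights q, output y_i = sum_j q_j M_ji
# ---------------------------------------------------------------------------

TSC_NAMES <- c("c", "L_n", "d_sq", "c_sq", "L_n_sq", "c_dsq", "c_Ln", "Ln_dsq")

#' Network architecture specification
#'
#' @param kind one of `"mixed"`, `"hypernetwork"`, `"modes"`.
#' @param main_widths hidden-layer widths of the main network `f_m`.
#' @param hyper_widths hidden-layer widths of the side network `f_h`
#'   (hypernetwork/modes kinds; must be empty for `"mixed"`).
#' @param use_tsc add the eight tube-specific coordinates to the coordinate
#'   inputs.
#' @param include_case concatenate the (normalized) case parameters to the
#'   main inputs; only meaningful (and default `TRUE`) for `"mixed"`.
#' @param n_outputs number of flow outputs (u, v, p), default 3.
#' @param n_modes number of modes B (`"modes"` kind only).
#' @param input_bias whether the first hidden layer of `f_m` carries a bias
#'   vector.  The published single-case totals are reproduced with
#'   `input_bias = FALSE`, the multi-case totals with `TRUE`.
#' @param hyper_feature width of the penultimate feature layer of `f_h`
#'   (default 10), after which a final affine layer emits the generated
#'   parameters (hypernetwork) or the flattened modes array (modes).
#' @return object of class `network_spec`.
#' @export
#' @examples
#' count_parameters(network_spec("mixed", rep(512, 4), use_tsc = FALSE,
#'                               include_case = FALSE, input_bias = FALSE))
network_spec <- function(kind = c("mixed", "hypernetwork", "modes"),
                         main_widths,
                         hyper_widths = if (kind == "mixed") integer() else rep(32L, 5L),
                         use_tsc = TRUE,
                         include_case = kind == "mixed",
                         n_outputs = 3L,
                         n_modes = NULL,
                         input_bias = TRUE,
                         hyper_feature = 10L) {
  kind <- match.arg(kind)
  main_widths <- as.integer(main_widths)
  hyper_widths <- as.integer(hyper_widths)
  stopifnot(all(main_widths >= 1L), n_outputs >= 1L)
  if (kind == "mixed" && length(hyper_widths)) {
    stop("mixed kind has no hypernetwork; hyper_widths must be empty")
  }
  if (kind != "mixed" && include_case) {
    stop("case parameters enter through f_h for kind = ", kind)
  }
  if (kind == "modes") {
    if (is.null(n_modes)) stop("modes kind requires n_modes (B >= 1)")
    n_modes <- as.integer(n_modes)
    stopifnot(n_modes >= 1L)
  } else if (!is.null(n_modes)) {
    stop("n_modes is only meaningful for the modes kind")
  }
  input_names <- c("x_n", "y_n",
                   if (use_tsc) TSC_NAMES,
                   if (include_case) c("A_n", "sigma_n"))
  structure(list(kind = kind, main_widths = main_widths,
                 hyper_widths = hyper_widths, use_tsc = use_tsc,
                 include_case = include_case, n_outputs = as.integer(n_outputs),
                 n_modes = n_modes, input_bias = isTRUE(input_bias),
                 hyper_feature = as.integer(hyper_feature),
                 input_names = input_names),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec [%s]: main %s, inputs (%d) %s%s%s\n",
              x$kind, paste(x$main_widths, collapse = "x"),
              length(x$input_names), paste(x$input_names, collapse = ","),
              if (length(x$hyper_widths))
                sprintf("; hyper %s + feature %d", paste(x$hyper_widths, collapse = "x"),
                        x$hyper_feature) else "",
              if (!is.null(x$n_modes)) sprintf("; B = %d", x$n_modes) else ""))
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

# layer sizes (fan_in, fan_out, has_bias) of a plain MLP
mlp_layers <- function(n_in, widths, n_out, input_bias) {
  sizes <- c(n_in, widths, n_out)
  L <- length(sizes) - 1L
  lapply(seq_len(L), function(l) {
    list(fan_in = sizes[l], fan_out = sizes[l + 1L],
         has_bias = (l > 1L) || input_bias)
  })
}

mlp_count <- function(n_in, widths, n_out, input_bias) {
  sum(vapply(mlp_layers(n_in, widths, n_out, input_bias), function(ly) {
    ly$fan_in * ly$fan_out + if (ly$has_bias) ly$fan_out else 0L
  }, 0))
}

#' Count trainable parameters of an architecture
#'
#' Exact count of trainable scalars.  For the hypernetwork kind only the
#' side-network parameters count (the main-network parameters are generated,
#' not trained); for the modes kind both networks count.
#'
#' @param spec a [network_spec()].
#' @return integer-valued count.
#' @export
count_parameters <- function(spec) {
  n_in <- length(spec$input_names)
  switch(spec$kind,
    mixed = mlp_count(n_in, spec$main_widths, spec$n_outputs, spec$input_bias),
    hypernetwork = {
      n_theta_m <- mlp_count(n_in, spec$main_widths, spec$n_outputs, spec$input_bias)
      mlp_count(2L, c(spec$hyper_widths, spec$hyper_feature), n_theta_m, TRUE)
    },
    modes = {
      mlp_count(n_in, spec$main_widths, spec$n_modes, spec$input_bias) +
        mlp_count(2L, c(spec$hyper_widths, spec$hyper_feature),
                  3L * spec$n_modes, TRUE)
    })
}

#' The published architecture triplets
#'
#' Builds the Mixed / Hypernetwork / Modes specifications at the two studied
#' parameter budgets.  All use the eight TSC inputs.  The number of modes B
#' defaults to the largest integer keeping the modes network within +0.1% of
#' the mixed-network budget.
#'
#' @param budget `"large"` (~2.2 M trainable parameters) or `"downsized"`
#'   (~0.8 M).
#' @return named list of three [network_spec()] objects
#'   (`mixed`, `hypernetwork`, `modes`).
#' @export
#' @examples
#' sapply(paper_architectures("large"), count_parameters)
paper_architectures <- function(budget = c("large", "downsized")) {
  budget <- match.arg(budget)
  mixed_w <- if (budget == "large") rep(856L, 4L) else rep(516L, 4L)
  hyper_feat <- if (budget == "large") 10L else 3L
  modes_w <- if (budget == "large") rep(851L, 3L) else rep(513L, 3L)
  mixed <- network_spec("mixed", mixed_w, use_tsc = TRUE,
                        include_case = TRUE, input_bias = TRUE)
  target <- count_parameters(mixed)
  hyper <- network_spec("hypernetwork", rep(256L, 4L),
                        hyper_widths = rep(32L, 5L), use_tsc = TRUE,
                        input_bias = TRUE, hyper_feature = hyper_feat)
  modes_count <- function(B) {
    count_parameters(network_spec("modes", modes_w, hyper_widths = rep(32L, 5L),
                                  use_tsc = TRUE, n_modes = B,
                                  input_bias = TRUE, hyper_feature = hyper_feat))
  }
  B <- 1L
  while (modes_count(B + 1L) <= target * 1.001) B <- B + 1L
  modes <- network_spec("modes", modes_w, hyper_widths = rep(32L, 5L),
                        use_tsc = TRUE, n_modes = B, input_bias = TRUE,
                        hyper_feature = hyper_feat)
  list(mixed = mixed, hypernetwork = hyper, modes = modes)
}

# --- parameter containers ---------------------------------------------------

# initialize a plain MLP: Glorot-normal weights, zero biases
mlp_init <- function(n_in, widths, n_out, input_bias, rng, scale = 1) {
  layers <- mlp_layers(n_in, widths, n_out, input_bias)
  W <- list(); b <- list()
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    sd <- sqrt(2 / (ly$fan_in + ly$fan_out)) * scale
    W[[l]] <- matrix(rng$rnorm(ly$fan_in * ly$fan_out, 0, sd), ly$fan_in, ly$fan_out)
    b[[l]] <- if (ly$has_bias) numeric(ly$fan_out) else NULL
  }
  list(W = W, b = b, layers = layers)
}

mlp_n_params <- function(p) {
  sum(vapply(seq_along(p$W), function(l) {
    length(p$W[[l]]) + length(p$b[[l]])
  }, 0))
}

mlp_flatten <- function(p) {
  unlist(lapply(seq_along(p$W), function(l) c(as.numeric(p$W[[l]]), p$b[[l]])))
}

mlp_unflatten <- function(p, theta) {
  pos <- 0L
  for (l in seq_along(p$W)) {
    nw <- length(p$W[[l]])
    p$W[[l]][] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(p$b[[l]])
    if (nb) {
      p$b[[l]] <- theta[pos + seq_len(nb)]
      pos <- pos + nb
    }
  }
  stopifnot(pos == length(theta))
  p
}

#' Initialize a PINN model
#'
#' Variance-scaled (Glorot) weight initialization with zero biases, seeded.
#' For the hypernetwork kind the final layer of `f_h` is initialized with
#' near-zero weights while its bias is set to a variance-scaled draw of the
#' generated main-network parameters, so the composite starts at a standard
#' initialization with weak case dependence.
#'
#' @param spec a [network_spec()].
#' @param ctx a [pinn_context()] (geometry constants, parameter ranges, fluid
#'   and normalization constants).
#' @param seed integer RNG seed.
#' @return object of class `pinn_model` with elements `spec`, `ctx`, `params`
#'   (`main` and, where present, `hyper`), and `meta` (seed, iterations).
#' @export
init_model <- function(spec, ctx = pinn_context(), seed = 1L) {
  rng <- local_rng(seed)
  n_in <- length(spec$input_names)
  params <- switch(spec$kind,
    mixed = list(main = mlp_init(n_in, spec$main_widths, spec$n_outputs,
                                 spec$input_bias, rng)),
    hypernetwork = {
      main_proto <- mlp_init(n_in, spec$main_widths, spec$n_outputs,
                             spec$input_bias, rng)
      n_theta_m <- mlp_n_params(main_proto)
      hyper <- mlp_init(2L, c(spec$hyper_widths, spec$hyper_feature),
                        n_theta_m, TRUE, rng)
      L <- length(hyper$W)
      hyper$W[[L]] <- hyper$W[[L]] * 1e-3
      hyper$b[[L]] <- mlp_flatten(main_proto)
      list(main_proto = main_proto, hyper = hyper)
    },
    modes = list(
      main = mlp_init(n_in, spec$main_widths, spec$n_modes,
                      spec$input_bias, rng),
      hyper = mlp_init(2L, c(spec$hyper_widths, spec$hyper_feature),
                       3L * spec$n_modes, TRUE, rng)))
  structure(list(spec = spec, ctx = ctx, params = params,
                 meta = list(seed = as.integer(seed), iterations = 0L)),
            class = "pinn_model")
}

#' @export
print.pinn_model <- function(x, ...) {
  cat("pinn_model (", x$spec$kind, "), ",
      format(count_parameters(x$spec), big.mark = ","),
      " trainable parameters, ", x$meta$iterations, " training iterations\n",
      sep = "")
  invisible(x)
}

# trainable parameter vector of a model (hypernetwork: theta_h only)
model_flatten <- function(model) {
  switch(model$spec$kind,
    mixed = mlp_flatten(model$params$main),
    hypernetwork = mlp_flatten(model$params$hyper),
    modes = c(mlp_flatten(model$params$main), mlp_flatten(model$params$hyper)))
}

model_unflatten <- function(model, theta) {
  switch(model$spec$kind,
    mixed = {
      model$params$main <- mlp_unflatten(model$params$main, theta)
    },
    hypernetwork = {
      model$params$hyper <- mlp_unflatten(model$params$hyper, theta)
    },
    modes = {
      n1 <- mlp_n_params(model$params$main)
      model$params$main <- mlp_unflatten(model$params$main, theta[seq_len(n1)])
      model$params$hyper <- mlp_unflatten(model$params$hyper, theta[-seq_len(n1)])
    })
  model
}

# SiLU activation and its derivatives up to fourth order, numerically stable
silu_derivs <- function(z, upto = 3L) {
  sg <- stats::plogis(z)
  sp <- sg * (1 - sg)
  spp <- sp * (1 - 2 * sg)
  out <- list(z * sg, sg + z * sp, 2 * sp + z * spp)
  if (upto >= 3L) {
    sppp <- spp * (1 - 2 * sg) - 2 * sp^2
    out[[4L]] <- 3 * spp + z * sppp
    if (upto >= 4L) {
      spppp <- sppp * (1 - 2 * sg) - 6 * sp * spp
      out[[5L]] <- 4 * sppp + z * spppp
    }
  }
  out
}
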