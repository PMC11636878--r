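# ---------------------------------------------------------------------------
# YAML run configuration with layered defaults and schema validation.
# ---------------------------------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    geometry = list(R0 = 0.05, x_center = 0.5, length = 1.0),
    fluid = list(rho = 1000, nu = 1.85e-6),
    normalization = list(V_kg = 1, V_m = 0.1, V_s = 10.811),
    inlet = list(u_max = 0.00925),
    cases = list(A_range = c(0.015, 0.035), sigma_range = c(0.10, 0.18),
                 n_A = 4L, n_sigma = 4L, validation_layout = c(9L, 5L)),
    architecture = list(kind = "mixed",
                        main_widths = c(856L, 856L, 856L, 856L),
                        hyper_widths = integer(),
                        use_tsc = TRUE, include_case = TRUE,
                        input_bias = TRUE, hyper_feature = 10L,
                        n_modes = NULL),
    training = list(counts = as.list(default_batch_counts()),
                    iterations = 1000L, iterations_per_epoch = 1000L,
                    pool_factor = 1000L, lr = 1e-3, lr_min = 1e-5,
                    betas = c(0.9, 0.999),
                    weights = list(w_physics = 1, w_bc = 1, w_derivative = 1),
                    gpinn_phase = "off", trace_every = 50L),
    evaluation = list(n_points = 10000L, n_wall = 200L),
    wss_convention = "as_printed")
}

merge_config <- function(base, user, path = character()) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], c(path, nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, key) if (!ok) errs <<- c(errs, key)
  known <- names(default_run_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) errs <- c(errs, paste0("unknown key: ", extra))
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed")
  chk(cfg$geometry$R0 > 0, "geometry.R0")
  chk(cfg$geometry$length > 0, "geometry.length")
  chk(cfg$fluid$rho > 0, "fluid.rho")
  chk(cfg$fluid$nu > 0, "fluid.nu")
  chk(all(unlist(cfg$normalization) > 0), "normalization")
  chk(cfg$inlet$u_max > 0, "inlet.u_max")
  chk(cfg$architecture$kind %in% c("mixed", "hypernetwork", "modes"),
      "architecture.kind")
  chk(all(unlist(cfg$architecture$main_widths) >= 1), "architecture.main_widths")
  chk(all(unlist(cfg$training$counts) >= 0) &&
        sum(unlist(cfg$training$counts)) > 0, "training.counts")
  chk(cfg$training$lr > 0, "training.lr")
  chk(cfg$training$iterations >= 0, "training.iterations")
  chk(cfg$wss_convention %in% c("as_printed", "conventional_2x"),
      "wss_convention")
  if (length(errs)) {
    stop("invalid run configuration; offending keys: ",
         paste(errs, collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML configuration and layers it over the package defaults
#' (every default equals the published study value where one exists).  The
#' shipped profile `paper_2d.yaml` (in `inst/config/`) spells out all
#' defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_run_config(cfg)
}

# materialize package objects from a run config
config_context <- function(cfg) {
  pinn_context(R0 = cfg$geometry$R0, x_center = cfg$geometry$x_center,
               length = cfg$geometry$length,
               A_range = as.numeric(unlist(cfg$cases$A_range)),
               sigma_range = as.numeric(unlist(cfg$cases$sigma_range)),
               u_max = cfg$inlet$u_max,
               fluid = fluid_properties(cfg$fluid$rho, cfg$fluid$nu),
               norms = normalization_constants(cfg$normalization$V_kg,
                                               cfg$normalization$V_m,
                                               cfg$normalization$V_s),
               wss_convention = cfg$wss_convention)
}

config_spec <- function(cfg) {
  a <- cfg$architecture
  network_spec(a$kind, unlist(a$main_widths),
               hyper_widths = unlist(a$hyper_widths),
               use_tsc = isTRUE(a$use_tsc),
               include_case = isTRUE(a$include_case),
               n_modes = a$n_modes,
               input_bias = isTRUE(a$input_bias),
               hyper_feature = a$hyper_feature)
}

config_training <- function(cfg, cases = NULL) {
  tr <- cfg$training
  if (is.null(cases)) {
    cg <- build_case_grid(cfg$cases$n_A, cfg$cases$n_sigma,
                          as.numeric(unlist(cfg$cases$A_range)),
                          as.numeric(unlist(cfg$cases$sigma_range)),
                          unlist(cfg$cases$validation_layout))
    cases <- cg$training
  }
  training_config(config_spec(cfg), config_context(cfg), cases = cases,
                  counts = unlist(tr$counts), iterations = tr$iterations,
                  iterations_per_epoch = tr$iterations_per_epoch,
                  pool_factor = tr$pool_factor, lr = tr$lr,
                  lr_min = tr$lr_min, betas = unlist(tr$betas),
                  weights = do.call(loss_weights, tr$weights),
                  gpinn_phase = tr$gpinn_phase, seed = cfg$seed,
                  trace_every = tr$trace_every)
}

# run manifest: everything needed to reproduce an artifact
write_manifest <- function(cfg, path, extra = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  manifest <- c(list(
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package = "tubepinn",
    version = as.character(utils::packageVersion("tubepinn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
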