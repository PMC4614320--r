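# allowed keys per config section; defaults come from the params constructors
config_sections <- list(
  three_layer = c("N", "n", "theta_ml", "theta_output", "beta", "a", "b", "c",
                  "w_max", "w_min", "eta0", "H0", "Hc", "active_fraction",
                  "init_weight_max"),
  homeostasis = c("n_nodes", "T", "morph_period", "theta", "beta", "p_del",
                  "nu", "lambda", "lambda_ext", "frac_excit", "window",
                  "init_indegree", "kernel_sigma"),
  lesion = c("kind", "m", "irt", "n_p", "start_time", "start_index"),
  eta = c("mode", "eta0", "H0", "Hc"),
  run = c("pre_duration", "recovery_steps", "post_window", "n_seeds", "seed",
          "out_dir", "scale", "gating")
)

# Table-name aliases accepted in config files
normalize_section <- function(section, values) {
  if (section == "homeostasis") {
    nm <- names(values)
    nm[nm == "T"] <- "morph_period"
    nm[nm == "lambda"] <- "lambda_ext"
    names(values) <- nm
  }
  values
}

#' Assemble and validate a run configuration
#'
#' A run configuration bundles everything needed to reproduce a simulation:
#' the model choice, its parameter section (three-layer or homeostasis
#' names; unspecified keys take the reference defaults of
#' [three_layer_params()] / [homeo_params()]), the lesion section
#' ([lesion_schedule()] fields), the eta section ([eta_policy()] fields,
#' three-layer only), and the run section (`pre_duration`, `recovery_steps`,
#' `post_window`, `n_seeds`, `seed`, `out_dir`, `scale`, `gating`). Unknown
#' keys are rejected. The homeostasis section also accepts the table names
#' `T` (for `morph_period`) and `lambda` (for `lambda_ext`).
#'
#' `scale = "scaled"` (the default for three-layer experiment presets) uses
#' N = 100, n = 20 so grids and paired tests run at desk scale; `"full"`
#' keeps the reference N = 500, n = 100.
#'
#' @param model `"three_layer"` or `"homeostasis"`.
#' @param three_layer,homeostasis,lesion,eta,run named lists of section
#'   overrides.
#' @return a validated object of class `run_config`.
#' @export
run_config <- function(model = c("three_layer", "homeostasis"),
                       three_layer = list(), homeostasis = list(),
                       lesion = list(), eta = list(), run = list()) {
  model <- match.arg(model)
  cfg <- list(model = model, three_layer = three_layer,
              homeostasis = homeostasis, lesion = lesion, eta = eta,
              run = run)
  as_run_config(cfg)
}

#' @rdname run_config
#' @param x a plain named list with the structure above.
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (!is.list(x)) cfg_stop("a run config must be a named list")
  known_top <- c("model", names(config_sections))
  bad <- setdiff(names(x), known_top)
  if (length(bad)) cfg_stop("unknown config section(s): %s", paste(bad, collapse = ", "))
  model <- x$model %||% "three_layer"
  if (!model %in% c("three_layer", "homeostasis")) {
    cfg_stop("model must be 'three_layer' or 'homeostasis' (got '%s')", model)
  }
  for (sec in names(config_sections)) {
    vals <- x[[sec]] %||% list()
    if (!is.list(vals)) cfg_stop("section '%s' must be a mapping", sec)
    bad <- setdiff(names(vals), config_sections[[sec]])
    if (length(bad)) {
      cfg_stop("unknown key(s) in section '%s': %s", sec, paste(bad, collapse = ", "))
    }
    x[[sec]] <- normalize_section(sec, vals)
  }
  x$model <- model
  # scale preset for the three-layer model
  scale <- x$run$scale %||% NULL
  if (!is.null(scale)) {
    if (!scale %in% c("scaled", "full")) cfg_stop("run$scale must be 'scaled' or 'full'")
    if (model == "three_layer" && scale == "scaled") {
      x$three_layer$N <- x$three_layer$N %||% 100L
      x$three_layer$n <- x$three_layer$n %||% 20L
    }
  }
  # eager validation of the pieces that will be used
  if (model == "three_layer") {
    do.call(three_layer_params, x$three_layer)
    do.call(eta_policy, x$eta)
  } else {
    do.call(homeo_params, x$homeostasis)
  }
  if (!is.null(x$lesion$kind) || !is.null(x$lesion$m)) {
    if (is.null(x$lesion$m)) cfg_stop("lesion section needs m when kind is given")
  }
  structure(x, class = "run_config")
}

#' Scaled three-layer experiment preset
#'
#' Convenience constructor for the desk-scale three-layer configuration used
#' by the package's paired experiments: N = 100, n = 20, fixed or modified
#' eta (with `H0 = 5`, `Hc = 15` when modified), master seed, and a lesion
#' section to fill per experiment.
#'
#' @param eta_mode `"fixed"` or `"modified"`.
#' @param seed master seed for derived per-trial seeds.
#' @param m defect size for the lesion section.
#' @param kind lesion kind.
#' @param irt inter-removal time.
#' @return a `run_config`.
#' @export
scaled_three_layer_config <- function(eta_mode = "fixed", seed = 1L,
                                      m = 16L, kind = "gradual", irt = 0) {
  run_config(
    model = "three_layer",
    eta = if (eta_mode == "modified") {
      list(mode = "modified", H0 = 5, Hc = 15)
    } else {
      list(mode = "fixed")
    },
    lesion = list(kind = kind, m = m, irt = irt),
    run = list(scale = "scaled", seed = seed)
  )
}

#' Default homeostasis experiment configuration
#'
#' The reference homeostasis run: Table-default model parameters, a gradual
#' lesion of `m` contiguous neurons starting after a 2700-morphological-step
#' burn-in.
#'
#' @param seed master seed.
#' @param m defect size.
#' @param irt inter-removal time (morphological steps).
#' @return a `run_config`.
#' @export
homeostasis_config <- function(seed = 1L, m = 10L, irt = 0) {
  run_config(
    model = "homeostasis",
    lesion = list(kind = "gradual", m = m, irt = irt, start_time = 2700L),
    run = list(seed = seed)
  )
}

#' Read a run configuration from a YAML file
#'
#' Loads, validates, and default-fills a structured text configuration (see
#' [run_config()] for the sections and keys). Errors name the offending key.
#'
#' @param path path to a YAML file.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) cfg_stop("config file not found: %s", path)
  as_run_config(yaml::read_yaml(path))
}

#' Write a run configuration to a YAML file
#'
#' Round-trips with [load_config()]: `load_config(write_config(cfg, path))`
#' equals `cfg`.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- as_run_config(config)
  out <- unclass(config)
  out <- out[c("model", names(config_sections))]
  out <- out[!vapply(out, function(v) is.null(v) || (is.list(v) && !length(v)), logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
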