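# Run configuration ------------------------------------------------------
#
# A validated key-value configuration (YAML, with JSON as a valid subset)
# tying the pipeline together: circuit, parameter overrides, input spec,
# design space, optimizer settings, noise model, seed and output
# directory.  Unknown keys are rejected by name; a write-then-read round
# trip reproduces the effective configuration exactly.

config_schema <- function() {
  list(
    model = c("unbuffered", "buffered"),
    params = "named",
    constants = "named",
    load_factor = "scalar",
    input = list(kind = c("step", "double_step", "square", "constant"),
                 magnitude = "scalar", onset = "scalar",
                 period = "scalar", second_onset = "scalar",
                 second_magnitude = "scalar"),
    design = list(input_kind = "scalar", u_lb = "scalar", u_ub = "scalar",
                  t_f = "scalar", n_m = "scalar", n_m_grid = "vector",
                  lambda = "scalar"),
    hs = list(hms = "scalar", hmcr = "scalar", par = "scalar",
              bw_frac = "scalar", max_iter = "scalar"),
    ga = list(pop_size = "scalar", mut_rate = "scalar",
              cross_rate = "scalar", mut_sd_frac = "scalar",
              max_iter = "scalar"),
    pso = list(swarm_size = "scalar", weight = "scalar", c1 = "scalar",
               c2 = "scalar", max_iter = "scalar"),
    noise = list(sigma_rel = "scalar", sigma_floor = "scalar",
                 clip = "scalar"),
    seed = "scalar",
    out_dir = "scalar"
  )
}

config_defaults <- function() {
  list(
    model = "unbuffered",
    params = list(),
    constants = list(),
    load_factor = 1,
    input = list(kind = "step", magnitude = 20, onset = 0,
                 period = NULL, second_onset = NULL,
                 second_magnitude = NULL),
    design = list(input_kind = "step", u_lb = 1, u_ub = 30, t_f = 3000,
                  n_m = 50, n_m_grid = seq(10, 100, by = 10),
                  lambda = 0.8),
    hs = list(hms = 15, hmcr = 0.8, par = 0.2, bw_frac = 0.05,
              max_iter = 2000),
    ga = list(pop_size = 50, mut_rate = 0.8, cross_rate = 0.2,
              mut_sd_frac = 0.1, max_iter = 200),
    pso = list(swarm_size = 50, weight = 1, c1 = 1, c2 = 1,
               max_iter = 200),
    noise = list(sigma_rel = 0.05, sigma_floor = 1e-3, clip = FALSE),
    seed = 1,
    out_dir = "."
  )
}

check_config_keys <- function(values, schema, path = "") {
  bad <- setdiff(names(values), names(schema))
  if (length(bad)) {
    stop("Unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  }
  for (key in names(values)) {
    rule <- schema[[key]]
    val <- values[[key]]
    here <- paste0(path, key)
    if (is.list(rule)) {
      if (!is.list(val)) {
        stop("Configuration key `", here, "` must be a mapping.",
             call. = FALSE)
      }
      check_config_keys(val, rule, paste0(here, "."))
    } else if (identical(rule, "named")) {
      if (length(val) && is.null(names(val))) {
        stop("Configuration key `", here, "` must be a named mapping.",
             call. = FALSE)
      }
    } else if (identical(rule, "scalar")) {
      if (!is.null(val) && length(val) != 1L) {
        stop("Configuration key `", here, "` must be a single value.",
             call. = FALSE)
      }
    } else if (is.character(rule) && length(rule) > 1L) {
      if (!val %in% rule) {
        stop("Configuration key `", here, "` must be one of: ",
             paste(rule, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

merge_config <- function(defaults, values) {
  for (key in names(values)) {
    if (is.list(defaults[[key]]) && is.list(values[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], values[[key]])
    } else {
      defaults[[key]] <- values[[key]]
    }
  }
  defaults
}

#' Build a validated run configuration
#'
#' @param ... Configuration entries overriding the defaults (see
#'   `config_defaults` in the package source for the full schema:
#'   `model`, `params`, `constants`, `load_factor`, `input`, `design`,
#'   `hs`, `ga`, `pso`, `noise`, `seed`, `out_dir`).
#' @return A `run_config` list with all defaults filled in.
#' @examples
#' cfg <- run_config(model = "buffered", seed = 42)
#' cfg$design$lambda
#' @export
run_config <- function(...) {
  values <- list(...)
  check_config_keys(values, config_schema())
  cfg <- merge_config(config_defaults(), values)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Validates against the schema (unknown keys are rejected by name) and
#' fills defaults.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("Configuration file not found: ", path, call. = FALSE)
  }
  values <- yaml::read_yaml(path)
  if (is.null(values)) values <- list()
  do.call(run_config, values)
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(drop_nulls(unclass(config)), path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' Instantiate the model, input and noise objects of a configuration
#'
#' @param config A [run_config()].
#' @return List with `model` ([circuit_model()]), `input`
#'   ([make_input()]), `design` ([design_space()]), `noise`
#'   ([noise_model()]) and `seed`.
#' @export
config_objects <- function(config) {
  stopifnot(inherits(config, "run_config"))
  model <- circuit_model(
    config$model,
    params = if (length(config$params)) unlist(config$params),
    constants = if (length(config$constants)) unlist(config$constants),
    load_factor = config$load_factor
  )
  inp <- config$input
  input <- make_input(inp$kind, magnitude = inp$magnitude,
                      onset = inp$onset %||% 0, period = inp$period,
                      second_onset = inp$second_onset,
                      second_magnitude = inp$second_magnitude)
  design <- design_space(input_kind = config$design$input_kind,
                         u_lb = config$design$u_lb,
                         u_ub = config$design$u_ub,
                         t_f = config$design$t_f,
                         n_m = config$design$n_m,
                         n_m_grid = config$design$n_m_grid,
                         lambda = config$design$lambda)
  noise <- noise_model(config$noise$sigma_rel, config$noise$sigma_floor,
                       isTRUE(config$noise$clip))
  list(model = model, input = input, design = design, noise = noise,
       seed = as.integer(config$seed))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> model:", x$model, " seed:", x$seed, "\n")
  cat(yaml::as.yaml(drop_nulls(unclass(x))))
  invisible(x)
}

#' Hyperparameters of a configuration as an [hs_config()]
#'
#' @param config A [run_config()].
#' @param seed Seed to attach.
#' @return An [hs_config()].
#' @export
config_hs <- function(config, seed = config$seed) {
  hs_config(hms = config$hs$hms, hmcr = config$hs$hmcr,
            par = config$hs$par, bw_frac = config$hs$bw_frac,
            max_iter = config$hs$max_iter, seed = seed)
}
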