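#' Load a run configuration
#'
#' Reads a JSON or YAML configuration with an optional `model` section
#' (fields of [model_params()]; absent keys take the standard defaults) and
#' an optional `run` section (mode and run-time settings). A flat file of
#' model keys alone is also accepted. Unknown keys are rejected with an
#' error naming the key, and the assembled parameter set is validated
#' eagerly.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return An object of class `run_config`: list with `model` (a validated
#'   `model_params`) and `run` (named list of run settings).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- read_config_file(path)
  model_keys <- setdiff(names(formals(model_params)), "")
  run_keys <- c("mode", "steps", "reps", "seed", "mu", "sigma",
                "sigma_initial", "sigma_after", "shock_step",
                "axis1_name", "axis1_values", "axis2_name", "axis2_values",
                "sigma_grid", "n_values", "window", "out")
  if (is.null(raw)) raw <- list()
  if (!any(c("model", "run") %in% names(raw)))
    raw <- list(model = raw, run = list()) # flat model-only file
  model <- if (is.null(raw$model)) list() else raw$model
  run <- if (is.null(raw$run)) list() else raw$run
  extra_top <- setdiff(names(raw), c("model", "run"))
  if (length(extra_top))
    stop("unknown top-level config key(s): ",
         paste(extra_top, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(model), model_keys)
  if (length(bad))
    stop("unknown model parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(names(run), run_keys)
  if (length(bad))
    stop("unknown run config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params <- do.call(model_params, model)
  structure(list(model = params, run = run), class = "run_config")
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format '", ext, "' (use .json or .yaml)",
         call. = FALSE)
  }
}

#' Save a run configuration
#'
#' Writes a `run_config` (or a bare `model_params`) so that
#' [load_config()] reproduces it exactly.
#'
#' @param config a `run_config` or `model_params` object.
#' @param path output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "model_params"))
    config <- structure(list(model = config, run = list()),
                        class = "run_config")
  obj <- list(model = unclass(config$model), run = config$run)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::write_yaml(obj, path)
  } else {
    stop("unsupported config format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Path to the bundled default configuration
#'
#' The package ships a configuration holding the standard parameter values
#' of the model (r = 0.1, x = 1, omega = 5, alpha = 1.2, beta = 5, pi = 10,
#' gamma = 1/3, T = 50, N = 500, n = 5, K = 50).
#' @return File path of the bundled JSON config.
#' @export
default_config_path <- function() {
  system.file("extdata", "table1_defaults.json", package = "desperation",
              mustWork = TRUE)
}

#' Export a policy map
#'
#' Writes the policy as a long-format CSV (`s`, `trustworthiness`, `action`,
#' `value`) plus a JSON sidecar (`<path>.json`) carrying the generating
#' parameters, grid metadata, terminal-fitness coefficients and params hash,
#' so the artifact is self-describing and [read_policy()] restores it
#' bit-identically.
#'
#' @param policy a [solve_policy()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "policy"))
  # %.17g so the numeric columns survive a write/read cycle bit-identically
  df <- data.frame(
    s = sprintf("%.17g", rep(policy$s, times = length(policy$q))),
    trustworthiness = sprintf("%.17g",
                              rep(policy$q, each = length(policy$s))),
    action = ACTION_LABELS[as.vector(policy$actions)],
    value = sprintf("%.17g", as.vector(policy$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(params = unclass(policy$params),
               params_hash = policy$params_hash,
               anchor = as.list(policy$anchor),
               terminal = as.list(policy$terminal),
               t = policy$t, last_change_t = policy$last_change_t,
               s_grid = c(min(policy$s), max(policy$s), length(policy$s)),
               q_grid = c(min(policy$q), max(policy$q), length(policy$q)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore a policy written by [write_policy()]
#'
#' @param path the CSV path previously written.
#' @return A `policy` object equal to the one written.
#' @export
read_policy <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- do.call(model_params, as.list(meta$params))
  ns <- meta$s_grid[3]
  np <- meta$q_grid[3]
  actions <- matrix(match(df$action, ACTION_LABELS), ns, np)
  values <- matrix(df$value, ns, np)
  structure(list(actions = actions, values = values,
                 s = seq(meta$s_grid[1], meta$s_grid[2], length.out = ns),
                 q = seq(meta$q_grid[1], meta$q_grid[2], length.out = np),
                 t = meta$t, params = params,
                 params_hash = meta$params_hash,
                 anchor = unlist(meta$anchor),
                 terminal = unlist(meta$terminal),
                 last_change_t = if (is.null(meta$last_change_t))
                   NA_integer_ else meta$last_change_t),
            class = "policy")
}

#' Export a simulation trace
#'
#' Writes the per-step trace as CSV and a JSON sidecar with the parameters,
#' seed and initial moments, enough metadata to rerun it exactly.
#'
#' @param trace a `sim_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sim_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(params = unclass(attr(trace, "params")),
               mu = attr(trace, "mu"), sigma = attr(trace, "sigma"),
               seed = attr(trace, "seed"),
               initial_mean = attr(trace, "initial_mean"),
               initial_sd = attr(trace, "initial_sd"),
               shock = as.list(attr(trace, "shock")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a configured experiment
#'
#' Dispatches a loaded configuration to the matching operation:
#' `"solve"` ([solve_policy()]), `"simulate"` ([run_simulation()]),
#' `"sweep"` ([phase_sweep()]), `"shock"` ([shock_experiment()]) or
#' `"critical-fraction"` ([critical_exploitation_fraction()]). If the run
#' section names an `out` path, the result is written there (policy or trace
#' CSV with JSON sidecar; sweep runs CSV).
#'
#' @param config a `run_config` from [load_config()], or a path to one.
#' @return The computed result object, invisibly when written to file.
#' @export
run_model <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$model
  run <- config$run
  mode <- if (is.null(run$mode)) "solve" else run$mode
  seed <- if (is.null(run$seed)) 1L else as.integer(run$seed)
  steps <- if (is.null(run$steps)) p$T else run$steps
  res <- switch(mode,
    solve = solve_policy(p),
    simulate = run_simulation(
      p, mu = if (is.null(run$mu)) p$mu else run$mu,
      sigma = if (is.null(run$sigma)) p$sigma else run$sigma,
      steps = steps, seed = seed),
    shock = shock_experiment(
      p, mu = if (is.null(run$mu)) p$mu else run$mu,
      sigma_initial = if (is.null(run$sigma_initial)) 4 else
        run$sigma_initial,
      sigma_after = if (is.null(run$sigma_after)) 3 else run$sigma_after,
      shock_step = if (is.null(run$shock_step)) 16 else run$shock_step,
      steps = steps, seed = seed),
    sweep = phase_sweep(
      p, axis1 = list(name = run$axis1_name,
                      values = as.numeric(run$axis1_values)),
      axis2 = list(name = run$axis2_name,
                   values = as.numeric(run$axis2_values)),
      reps = if (is.null(run$reps)) 5 else run$reps,
      seed = seed, steps = steps),
    `critical-fraction` = critical_exploitation_fraction(
      p, sigma_grid = as.numeric(run$sigma_grid),
      reps = if (is.null(run$reps)) 5 else run$reps,
      seed = seed, steps = steps),
    stop("unknown run mode '", mode, "'", call. = FALSE))
  if (!is.null(run$out)) {
    if (inherits(res, "policy")) write_policy(res, run$out)
    else if (inherits(res, "sim_trace")) write_trace(res, run$out)
    else if (inherits(res, "sweep_result"))
      utils::write.csv(res$runs, run$out, row.names = FALSE)
    else jsonlite::write_json(res[setdiff(names(res), "runs")], run$out,
                              auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}
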