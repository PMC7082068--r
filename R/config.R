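#' Load and validate a run configuration
#'
#' A run configuration is a YAML (or JSON) mapping tying a fit together:
#' file paths, parameter-space and penalty settings, sampler settings and
#' reduction settings. Unknown keys are rejected (with a nearest-match
#' suggestion, to catch typos) and defaults are filled in, so the returned
#' object is fully resolved and serializes deterministically.
#'
#' Top-level keys: `network` (path), `data` (path), `mode`
#' (`pt`/`ptlasso`/`grouped`), `seed`, `output_dir`, and the blocks
#' `parameter_space` (`lower`, `upper`, `mu`, `b`), `grouped` (`mu`, `b`,
#' `lb`, `ub`, `lambda_lower`, `lambda_upper`), `constraints` (`hard`:
#' list of inequality strings), `sampler` (`n_chains`, `beta_min`,
#' `n_swaps`, `n_mcmc`, `burn_in`, `adapt`, `target_accept`, `eta`,
#' `scale0`, `init_threshold`) and `reduction` (`c_boundary`,
#' `mass_threshold`, `active_threshold`, `b_grid`).
#'
#' @param path config file path.
#' @return an object of class `"run_config"` (a fully resolved named list).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stop("config must be a mapping")
  resolve_config(y, where = path)
}

config_schema <- function() {
  list(
    network = NULL, data = NULL, mode = "ptlasso", seed = 1L,
    output_dir = ".",
    parameter_space = list(lower = -12, upper = 3, mu = -10, b = 1),
    grouped = list(mu = -25, b = 2, lb = -5, ub = 10,
                   lambda_lower = -35, lambda_upper = 6),
    constraints = list(hard = list()),
    sampler = list(n_chains = 6L, beta_min = 0.05, n_swaps = 1000L,
                   n_mcmc = 25L, burn_in = 200L, adapt = TRUE,
                   target_accept = 0.234, eta = 0.5, scale0 = 0.5,
                   init_threshold = Inf),
    reduction = list(c_boundary = 3, mass_threshold = 0.9,
                     active_threshold = -5, b_grid = c(0.1, 0.5, 1, 2)))
}

resolve_config <- function(y, where = "config") {
  schema <- config_schema()
  check_keys(names(y), names(schema), where)
  out <- schema
  for (k in names(y)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      if (!is.list(y[[k]]))
        stop(sprintf("config key '%s' must be a mapping", k))
      check_keys(names(y[[k]]), names(schema[[k]]),
                 paste0(where, ":", k))
      for (k2 in names(y[[k]])) out[[k]][[k2]] <- y[[k]][[k2]]
    } else {
      out[[k]] <- y[[k]]
    }
  }
  if (!out$mode %in% c("pt", "ptlasso", "grouped"))
    stop("config 'mode' must be one of pt, ptlasso, grouped")
  structure(out, class = "run_config")
}

check_keys <- function(keys, known, where) {
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, known)
      if (min(d) <= 2) sprintf(" (did you mean '%s'?)",
                               known[which.min(d)]) else ""
    }, character(1))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste0("'", unknown, "'", hints, collapse = ", ")))
  }
}

#' Write a resolved run configuration
#'
#' @param config a `"run_config"`.
#' @param path output YAML path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- unclass(config)
  # YAML has no native Inf; store as the string ".inf" convention
  if (is.infinite(y$sampler$init_threshold))
    y$sampler$init_threshold <- ".inf"
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Execute a fit described by a run configuration
#'
#' Loads the network and data named by the config, runs the configured
#' fit, and writes the sample store (`samples.tsv`), the acceptance report
#' (`acceptance.tsv`), the reduction report (`reduction.tsv`, penalized
#' modes only) and the resolved configuration (`config_resolved.yaml`)
#' into the output directory.
#'
#' @param config a `"run_config"` from [load_run_config()].
#' @param mode override the config's mode.
#' @param seed override the config's seed.
#' @param output_dir override the config's output directory.
#' @return the `"ptlasso_fit"`, invisibly.
#' @export
run_config_fit <- function(config, mode = NULL, seed = NULL,
                           output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(mode)) config$mode <- mode
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  if (is.null(config$network)) stop("config is missing 'network'")
  if (is.null(config$data))
    stop("config is missing 'data' (required to fit)")
  network <- read_network(config$network)
  obs <- read_observed(config$data)
  thr <- config$sampler$init_threshold
  if (identical(thr, ".inf")) thr <- Inf
  st <- pt_settings(
    n_chains = config$sampler$n_chains,
    beta_min = config$sampler$beta_min,
    n_swaps = config$sampler$n_swaps, n_mcmc = config$sampler$n_mcmc,
    burn_in = config$sampler$burn_in, adapt = config$sampler$adapt,
    target_accept = config$sampler$target_accept,
    eta = config$sampler$eta, scale0 = config$sampler$scale0)
  cons <- if (length(config$constraints$hard))
    hard_constraints(unlist(config$constraints$hard))
  penalty <- switch(config$mode, pt = "none", ptlasso = "lasso",
                    grouped = "grouped")
  fit <- ptlasso(
    network, obs,
    penalty = penalty,
    mu = config$parameter_space$mu, b = config$parameter_space$b,
    bounds = c(config$parameter_space$lower, config$parameter_space$upper),
    grouped = grouped_spec(
      mu = config$grouped$mu, b = config$grouped$b,
      lb = config$grouped$lb, ub = config$grouped$ub,
      lambda_lower = config$grouped$lambda_lower,
      lambda_upper = config$grouped$lambda_upper),
    constraints = cons, settings = st, seed = config$seed,
    init_threshold = thr)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  write_samples(fit, out("samples.tsv"))
  acc <- acceptance_report(fit)
  utils::write.table(acc$steps, out("acceptance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (penalty != "none") {
    cls <- classify_parameters(
      fit, c_boundary = config$reduction$c_boundary,
      mass_threshold = config$reduction$mass_threshold)
    utils::write.table(cls$table, out("reduction.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_run_config(config, out("config_resolved.yaml"))
  invisible(fit)
}
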