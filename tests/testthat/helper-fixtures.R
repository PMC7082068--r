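# Shared fixtures and scaled-down sampler settings for the test suite.
# Expensive end-to-end fits are computed once and reused across test
# blocks via a session-local cache.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

quick_settings <- function(...) {
  pt_settings(n_chains = 3, n_swaps = 60, n_mcmc = 5, burn_in = 20, ...)
}

# study-condition settings for the benchmark fits (desk scale)
k3_settings <- function()
  pt_settings(n_chains = 6, n_swaps = 1500, n_mcmc = 25, burn_in = 300)

k5_settings <- function()
  pt_settings(n_chains = 6, n_swaps = 2000, n_mcmc = 25, burn_in = 400)

dose_linear_settings <- function()
  pt_settings(n_chains = 6, n_swaps = 2000, n_mcmc = 20, burn_in = 600)

dose_adapting_settings <- function()
  pt_settings(n_chains = 6, n_swaps = 3500, n_mcmc = 15, burn_in = 1500)

toy_settings <- function()
  pt_settings(n_chains = 6, n_swaps = 1000, n_mcmc = 15, burn_in = 400)

k3_data <- function() cached("k3_data", generate_dataset("k3", seed = 1))

k3_fit <- function(seed = 101, penalty = "lasso") {
  cached(paste0("k3_fit_", penalty, "_", seed), {
    obs <- k3_data()
    ptlasso(attr(obs, "network"), obs, penalty = penalty,
            mu = -10, b = 1, bounds = c(-12, 3),
            settings = k3_settings(), seed = seed)
  })
}

k5_fit <- function(seed = 101) {
  cached(paste0("k5_fit_", seed), {
    obs <- generate_dataset("k5", seed = 1)
    ptlasso(attr(obs, "network"), obs, penalty = "lasso",
            mu = -10, b = 1, bounds = c(-12, 3),
            settings = k5_settings(), seed = seed)
  })
}

dose_linear_fit <- function() {
  cached("dose_linear_fit", {
    obs <- generate_dataset("dose-linear", seed = 1)
    ptlasso(attr(obs, "network"), obs,
            experiments = attr(obs, "experiments"), penalty = "lasso",
            mu = -10, b = 0.5, bounds = c(-12, 6),
            settings = dose_linear_settings(), seed = 301)
  })
}

dose_adapting_fit <- function() {
  cached("dose_adapting_fit", {
    obs <- generate_dataset("dose-adapting", seed = 1)
    ptlasso(attr(obs, "network"), obs,
            experiments = attr(obs, "experiments"), penalty = "lasso",
            mu = -10, b = 1, bounds = c(-12, 6),
            settings = dose_adapting_settings(), seed = 302)
  })
}

toy_fit <- function(protocol) {
  cached(paste0("toy_fit_", protocol), {
    obs <- generate_modular_toy_data(protocol, seed = 1)
    ptlasso(attr(obs, "network"), obs,
            experiments = attr(obs, "experiments"), penalty = "grouped",
            grouped = grouped_spec(mu = -25, b = 2, lb = -5, ub = 10),
            settings = toy_settings(), seed = 401)
  })
}
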