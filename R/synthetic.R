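#' Generate noisy observed data from a true trajectory
#'
#' Simulates the network at the true rate constants on a fine grid, then at
#' each observation point adds independent Gaussian noise to each of
#' `n_rep` replicates and returns the per-point replicate mean and standard
#' deviation as the "observed data" used for fitting. By default the noise
#' sd is `noise_frac` times the absolute true value; `noise_on =
#' "variance"` instead makes the noise *variance* that fraction of the true
#' value. Negative noisy replicates are kept as-is (the noise is additive);
#' degenerate zero sds are handled later by the likelihood sigma floor.
#'
#' @param network a [reaction_network()].
#' @param theta_true named numeric vector of true rate constants in linear
#'   space; parameters not named are set to 0 (reaction absent).
#' @param obs_times observation time points (subset of the fine grid).
#' @param species observed species (default: all).
#' @param noise_frac noise fraction (>= 0).
#' @param n_rep number of replicates (>= 2).
#' @param inputs stimulus schedule (default `network$inputs`).
#' @param fine_times fine simulation grid; defaults to 100 points over the
#'   observation window plus the observation times.
#' @param noise_on `"sd"` (noise sd = frac x |truth|) or `"variance"`.
#' @param seed optional seed making the dataset bit-reproducible.
#' @param experiment experiment label for the output records.
#' @return an `"observed_data"` data.frame (experiment, species, time, mean,
#'   sd) with a `provenance` attribute sufficient to regenerate it.
#' @export
generate_observed <- function(network, theta_true, obs_times,
                              species = network$species,
                              noise_frac = 0.3, n_rep = 10,
                              inputs = network$inputs, fine_times = NULL,
                              noise_on = c("sd", "variance"), seed = NULL,
                              experiment = "1") {
  noise_on <- match.arg(noise_on)
  if (noise_frac < 0) stop("'noise_frac' must be >= 0")
  if (n_rep < 2) stop("'n_rep' must be >= 2")
  k <- full_params(network, theta_true)
  if (is.null(fine_times))
    fine_times <- sort(unique(c(seq(0, max(obs_times), length.out = 100),
                                obs_times)))
  if (!all(obs_times %in% fine_times))
    stop("'obs_times' must be a subset of the fine grid")
  traj <- tryCatch(
    simulate_network(network, k, fine_times, inputs = inputs),
    error = function(e) stop("truth must be simulable: ",
                             conditionMessage(e)))
  grid <- expand.grid(time = obs_times, species = species,
                      stringsAsFactors = FALSE)
  truth <- trajectory_value(traj, grid$species, grid$time)
  noise_sd <- if (noise_on == "sd") noise_frac * abs(truth) else
    sqrt(noise_frac * abs(truth))
  reps <- with_preserved_rng({
    if (!is.null(seed)) set.seed(seed)
    vapply(seq_len(n_rep), function(r)
      truth + stats::rnorm(length(truth)) * noise_sd,
      numeric(length(truth)))
  })
  out <- data.frame(experiment = experiment, species = grid$species,
                    time = grid$time,
                    mean = rowMeans(reps),
                    sd = apply(reps, 1, stats::sd),
                    stringsAsFactors = FALSE)
  structure(out, class = c("observed_data", "data.frame"),
            provenance = list(
              generator = "generate_observed",
              theta_true = as.list(theta_true), obs_times = obs_times,
              species = species, noise_frac = noise_frac, n_rep = n_rep,
              noise_on = noise_on, seed = seed, experiment = experiment),
            truth = traj)
}

full_params <- function(network, theta_true) {
  pars <- network_params(network)
  k <- stats::setNames(numeric(length(pars)), pars)
  if (length(theta_true)) {
    if (is.null(names(theta_true)) ||
        !all(names(theta_true) %in% pars))
      stop("'theta_true' must be named by the network's rate parameters")
    k[names(theta_true)] <- theta_true
  }
  k
}

#' Generate observed data from noise on the log parameters
#'
#' Instead of perturbing the trajectory, perturbs the log10 true parameters
#' with Gaussian noise (sd `sd_log`) independently for each replicate,
#' simulates every perturbed parameter set, and returns the pointwise mean
#' and sd of the replicate model outputs as the observed data — a model of
#' cell-to-cell parameter variability rather than measurement error.
#' Replicate rate constants are thus log-normally distributed around the
#' truth.
#'
#' @param network a [reaction_network()].
#' @param log_theta_true named log10 true parameters; parameters not named
#'   are held at exactly 0 (reaction absent, never perturbed).
#' @param sd_log Gaussian sd of the log10 perturbation (>= 0).
#' @inheritParams generate_observed
#' @return an `"observed_data"` data.frame as in [generate_observed()].
#' @export
generate_param_noise_observed <- function(network, log_theta_true,
                                          obs_times,
                                          species = network$species,
                                          sd_log = 0.05, n_rep = 10,
                                          inputs = network$inputs,
                                          seed = NULL, experiment = "1") {
  if (sd_log < 0) stop("'sd_log' must be >= 0")
  if (n_rep < 2) stop("'n_rep' must be >= 2")
  if (is.null(names(log_theta_true)) ||
      !all(names(log_theta_true) %in% network_params(network)))
    stop("'log_theta_true' must be named by the network's rate parameters")
  grid <- expand.grid(time = obs_times, species = species,
                      stringsAsFactors = FALSE)
  reps <- with_preserved_rng({
    if (!is.null(seed)) set.seed(seed)
    vapply(seq_len(n_rep), function(r) {
      lt <- log_theta_true + stats::rnorm(length(log_theta_true)) * sd_log
      k <- full_params(network, stats::setNames(10^lt,
                                                names(log_theta_true)))
      traj <- tryCatch(
        simulate_network(network, k, sort(unique(obs_times)),
                         inputs = inputs),
        error = function(e)
          stop(sprintf("replicate %d failed to simulate: %s", r,
                       conditionMessage(e))))
      trajectory_value(traj, grid$species, grid$time)
    }, numeric(nrow(grid)))
  })
  out <- data.frame(experiment = experiment, species = grid$species,
                    time = grid$time,
                    mean = rowMeans(reps),
                    sd = apply(reps, 1, stats::sd),
                    stringsAsFactors = FALSE)
  structure(out, class = c("observed_data", "data.frame"),
            provenance = list(
              generator = "generate_param_noise_observed",
              log_theta_true = as.list(log_theta_true),
              obs_times = obs_times, species = species, sd_log = sd_log,
              n_rep = n_rep, seed = seed, experiment = experiment))
}

#' Dose-response experiment protocols
#'
#' Builds the experiment list for the dose-response benchmarks. The
#' `"linear"` protocol runs one constant-signal experiment per dose
#' (default S = 1, 2, 3, 4), each observed at 4 time points including
#' t = 0 — 16 observation records in total. The `"adapting"` protocol is a
#' single experiment whose signal steps through two successive values
#' (default S = 1 then 2, switching halfway through the window).
#'
#' The default observation grids are chosen to expose the defining feature
#' of each response: the linear protocol observes up to t = 600 s so the
#' response saturates at its dose-proportional plateau R* = (k_srs/k_r0) S
#' (which is what identifies the decay rate), and the adapting protocol
#' places points on the fast post-step transients (relaxation timescale
#' ~1/(k_xrx X) ~ 0.1 s) and samples both adapted plateaus densely enough
#' to pin the level-independent steady state (which is what distinguishes
#' the leaky-intermediate adaptive motif from an integral-control variant
#' whose plateau droops over time).
#'
#' @param type `"linear"` or `"adapting"`.
#' @param doses signal levels for the linear protocol; an empty vector
#'   yields an empty experiment list.
#' @param steps the two successive signal levels of the adapting protocol.
#' @param obs_times observation grid; defaults to 4 points including t = 0
#'   over [0, 600] s (linear) or 12 points over (0, 10] s straddling the
#'   step at t = 5 s (adapting).
#' @return list of experiments, each `list(id, inputs, obs_times)`.
#' @export
dose_response_protocol <- function(type = c("linear", "adapting"),
                                   doses = 1:4, steps = c(1, 2),
                                   obs_times = NULL) {
  type <- match.arg(type)
  if (type == "linear") {
    if (!length(doses)) return(list())
    if (is.null(obs_times)) obs_times <- seq(0, 600, length.out = 4)
    tmax <- max(obs_times)
    lapply(doses, function(d) list(
      id = paste0("S", d),
      inputs = data.frame(name = "S", value = d, start = 0, end = tmax),
      obs_times = obs_times))
  } else {
    if (length(steps) != 2) stop("'steps' must give two signal levels")
    if (is.null(obs_times))
      obs_times <- c(0.25, 0.75, 1.5, 2.5, 3.5, 4.5,
                     5.25, 5.75, 6.5, 7.5, 8.5, 10)
    tmax <- max(obs_times)
    t_step <- 5
    list(list(
      id = "step",
      inputs = data.frame(name = "S", value = steps,
                          start = c(0, t_step),
                          end = c(t_step, max(tmax, t_step) + 1)),
      obs_times = obs_times))
  }
}

#' True rate constants of the benchmark generative models
#'
#' `"k3"`/`"k5"`: the A -> B -> C pulse-generator motif (k_AB = 0.1 s^-1,
#' k_BC = 1 s^-1) embedded in the complete 3- or 5-node network.
#' `"dose-linear"`: the linear dose-response submodel (k_srs = 10 s^-1,
#' k_r0 = 0.01 s^-1). `"dose-adapting"`: the perfectly adapting submodel
#' (k_srs = 10 s^-1, k_xrx = 10 molecule^-1 s^-1, k_sxs = 1 s^-1,
#' k_x0 = 1 s^-1). Unnamed parameters are 0.
#'
#' @param fixture fixture name.
#' @return named numeric vector of true rate constants (linear space).
#' @export
true_params <- function(fixture = c("k3", "k5", "dose-linear",
                                    "dose-adapting")) {
  fixture <- match.arg(fixture)
  switch(fixture,
         "k3" = ,
         "k5" = c(k_AB = 0.1, k_BC = 1),
         "dose-linear" = c(k_srs = 10, k_r0 = 0.01),
         "dose-adapting" = c(k_srs = 10, k_xrx = 10, k_sxs = 1, k_x0 = 1))
}

#' Observation time grid for the complete-network benchmarks
#'
#' Eight evenly spaced points over (0, 30] s; the grid excludes t = 0 where
#' the observed species B is identically zero.
#'
#' @return numeric vector of 8 times (s).
#' @export
k3_observation_times <- function() seq(30 / 8, 30, length.out = 8)

#' Generate a benchmark observed dataset
#'
#' One-call generators for the study datasets: `"k3"`/`"k5"` observe
#' species B of the pulse-generator motif at 8 time points with 10
#' replicates of 30% trajectory noise; `"dose-linear"` observes R for
#' doses S = 1..4 at 4 time points each (10% noise); `"dose-adapting"`
#' observes R under the two-step signal protocol (10% noise);
#' `"k3-paramnoise"` perturbs the log10 truth (sd 0.05) instead of the
#' trajectory.
#'
#' @param fixture dataset name.
#' @param seed seed for the noise draws.
#' @param n_rep number of replicates.
#' @return an `"observed_data"` data.frame; for the dose-response fixtures
#'   the `experiments` attribute holds the named stimulus schedules to pass
#'   to [ptlasso()] or [energy_model()].
#' @export
generate_dataset <- function(fixture = c("k3", "k5", "dose-linear",
                                         "dose-adapting", "k3-paramnoise"),
                             seed = 1L, n_rep = 10) {
  fixture <- match.arg(fixture)
  if (fixture %in% c("k3", "k5")) {
    net <- complete_unimolecular_network(if (fixture == "k3") 3 else 5)
    out <- generate_observed(net, true_params(fixture),
                             obs_times = k3_observation_times(),
                             species = "B", noise_frac = 0.3,
                             n_rep = n_rep, seed = seed)
    attr(out, "network") <- net
    return(out)
  }
  if (fixture == "k3-paramnoise") {
    net <- complete_unimolecular_network(3)
    out <- generate_param_noise_observed(
      net, log_theta_true = c(k_AB = -1, k_BC = 0),
      obs_times = k3_observation_times(), species = "B", sd_log = 0.05,
      n_rep = n_rep, seed = seed)
    attr(out, "network") <- net
    return(out)
  }
  net <- dose_response_network()
  type <- if (fixture == "dose-linear") "linear" else "adapting"
  proto <- dose_response_protocol(type)
  truth <- true_params(if (type == "linear") "dose-linear"
                       else "dose-adapting")
  parts <- lapply(seq_along(proto), function(i) {
    ex <- proto[[i]]
    generate_observed(net, truth, obs_times = ex$obs_times, species = "R",
                      noise_frac = 0.1, n_rep = n_rep, inputs = ex$inputs,
                      seed = seed + i - 1L, experiment = ex$id)
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  structure(out, class = c("observed_data", "data.frame"),
            provenance = list(generator = "generate_dataset",
                              fixture = fixture, seed = seed,
                              n_rep = n_rep),
            experiments = stats::setNames(
              lapply(proto, `[[`, "inputs"),
              vapply(proto, `[[`, character(1), "id")),
            network = net)
}

#' Generate observed data for the modular toy network
#'
#' Observes species R of [modular_toy_network()] at the true rates under
#' the chosen stimulus protocol, with 10% trajectory noise.
#'
#' @param protocol `"pulse"` or `"continuous"`.
#' @param seed seed for the noise draws.
#' @param n_rep number of replicates.
#' @return an `"observed_data"` data.frame with the protocol schedule in the
#'   `experiments` attribute.
#' @export
generate_modular_toy_data <- function(protocol = c("pulse", "continuous"),
                                      seed = 1L, n_rep = 10) {
  protocol <- match.arg(protocol)
  net <- modular_toy_network()
  sch <- modular_toy_protocol(protocol)
  out <- generate_observed(net, modular_toy_truth(),
                           obs_times = modular_toy_observation_times(protocol),
                           species = "R", noise_frac = 0.1, n_rep = n_rep,
                           inputs = sch, seed = seed, experiment = protocol)
  attr(out, "experiments") <- stats::setNames(list(sch), protocol)
  attr(out, "network") <- net
  out
}

#' Regenerate an observed dataset from its provenance
#'
#' Rebuilds a dataset from the provenance metadata embedded by the
#' generators; with the same network and seed the result is bit-identical.
#'
#' @param network the [reaction_network()] the data were generated from
#'   (ignored for `generate_dataset` provenance, which knows its fixture).
#' @param provenance a provenance list, e.g. `attr(obs, "provenance")`.
#' @param inputs stimulus schedule if the original generation used one.
#' @return an `"observed_data"` data.frame.
#' @export
regenerate_observed <- function(network, provenance, inputs = NULL) {
  gen <- provenance$generator
  if (gen == "generate_dataset")
    return(generate_dataset(provenance$fixture, seed = provenance$seed,
                            n_rep = provenance$n_rep))
  if (gen == "generate_observed")
    return(generate_observed(
      network, unlist(provenance$theta_true), provenance$obs_times,
      species = provenance$species, noise_frac = provenance$noise_frac,
      n_rep = provenance$n_rep, inputs = inputs,
      noise_on = provenance$noise_on, seed = provenance$seed,
      experiment = provenance$experiment))
  if (gen == "generate_param_noise_observed")
    return(generate_param_noise_observed(
      network, unlist(provenance$log_theta_true), provenance$obs_times,
      species = provenance$species, sd_log = provenance$sd_log,
      n_rep = provenance$n_rep, inputs = inputs, seed = provenance$seed,
      experiment = provenance$experiment))
  stop("unknown generator in provenance: ", gen)
}
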