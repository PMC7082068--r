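#' Gaussian log likelihood of a trajectory against observed data
#'
#' Computes the unnormalized Gaussian log likelihood
#' -sum over records (Ysim - Yexpt)^2 / (2 sigma^2); the normalization
#' constant is dropped (it cancels in Metropolis ratios). sigma is the
#' per-record standard deviation of the observed data, floored at
#' `max(sd_floor, 0.01 * max(mean))` because replicate standard deviations
#' vanish at points where the true value is zero.
#'
#' @param traj a `"trajectory"` covering every (species, time) record of
#'   `obs`; a missing record is an error.
#' @param obs data.frame with columns species, time, mean, sd.
#' @param sd_floor minimum allowed sigma before the relative floor; default 0.
#' @return scalar log likelihood (0 for a perfect fit); `-Inf` if the
#'   trajectory contains non-finite values.
#' @examples
#' tr <- structure(list(times = 1, values = cbind(A = 2)), class = "trajectory")
#' log_likelihood(tr, data.frame(species = "A", time = 1, mean = 1, sd = 1))
#' @export
log_likelihood <- function(traj, obs, sd_floor = 0) {
  if (any(!is.finite(traj$values))) return(-Inf)
  sim <- trajectory_value(traj, obs$species, obs$time)
  sigma <- floor_sd(obs$sd, obs$mean, sd_floor)
  -sum((sim - obs$mean)^2 / (2 * sigma^2))
}

floor_sd <- function(sd, mean, sd_floor = 0) {
  pmax(sd, max(sd_floor, 1e-2 * max(abs(mean))))
}

#' Build a posterior energy model
#'
#' Assembles the posterior energy E(theta) = -log L(theta) - log p(theta)
#' (up to dropped constants) for a reaction network, observed time-course
#' data and a parameter space, and returns a model object whose `$energy`
#' element evaluates it for a log10 parameter vector. The energy is +Inf
#' when any parameter leaves its sampling box, any hard constraint is
#' violated, or the ODE integration fails; uniform priors contribute 0
#' inside their box and Laplace priors contribute |theta - mu| / b. Soft
#' constraints add their finite quadratic penalties.
#'
#' With `grouped` set, the sampled vector is the concatenation of one
#' penalty parameter per module (named `lambda_<module>`, Laplace-penalized)
#' and one reaction-specific parameter per reaction (named as the rate
#' parameter, confined to the open interval (lb, ub)); the effective log10
#' rate constant of reaction i in module m is k'_i + lambda'_m.
#'
#' @param network a [reaction_network()].
#' @param data observed data: data.frame with columns species, time, mean,
#'   sd, and optionally experiment (matching names of `experiments`).
#' @param space a [parameter_space()] over the network's rate parameters.
#'   Ignored (rebuilt internally) when `grouped` is given.
#' @param experiments named list of stimulus schedules, one per experiment
#'   level in `data`; `NULL` uses `network$inputs` for a single experiment.
#' @param constraints a [hard_constraints()] object or `NULL`.
#' @param soft list of [soft_constraint()] objects or `NULL`.
#' @param grouped a [grouped_spec()] to use the module-level penalty; the
#'   network must carry module labels.
#' @param sd_floor minimum likelihood sigma (see [log_likelihood()]).
#' @param rtol,atol integrator tolerances.
#' @return an object of class `"energy_model"` with elements `energy`
#'   (function(theta) -> scalar), `space` (the sampled space),
#'   `loglik` (function(theta) -> log likelihood only), and metadata.
#' @export
energy_model <- function(network, data, space = NULL, experiments = NULL,
                         constraints = NULL, soft = NULL, grouped = NULL,
                         sd_floor = 0, rtol = 1e-6, atol = 1e-9) {
  pars <- network_params(network)
  data <- as.data.frame(data)
  if (!all(c("species", "time", "mean", "sd") %in% names(data)))
    stop("'data' needs columns species, time, mean, sd")
  if (is.null(data$experiment)) data$experiment <- "1"
  exp_ids <- unique(data$experiment)
  if (is.null(experiments))
    experiments <- stats::setNames(rep(list(network$inputs), length(exp_ids)),
                                   exp_ids)
  if (!all(exp_ids %in% names(experiments)))
    stop("missing stimulus schedule for experiment(s): ",
         paste(setdiff(exp_ids, names(experiments)), collapse = ", "))
  sigma_all <- floor_sd(data$sd, data$mean, sd_floor)

  # per-experiment simulation contexts
  ctx <- lapply(exp_ids, function(id) {
    rows <- which(data$experiment == id)
    obs <- data[rows, ]
    times <- sort(unique(obs$time))
    inputs <- validate_schedule(experiments[[id]], network$species)
    linear <- is.null(inputs) && is_linear_conversion(network)
    list(id = id, rows = rows, times = times,
         it = match(obs$time, times),
         is = match(obs$species, network$species),
         inputs = inputs, linear = linear,
         sim = compile_sim_ctx(network, if (is.null(inputs)) character()
                               else unique(inputs$name)))
  })

  # Multi-experiment likelihoods where every experiment observes the same
  # time grid under inputs that are constant over the whole window can be
  # integrated as one stacked system in a single integrator call.
  stackable <- length(ctx) > 1 &&
    all(vapply(ctx, function(cc) {
      if (is.null(cc$inputs)) return(FALSE)
      s <- cc$inputs
      identical(cc$times, ctx[[1]]$times) &&
        !anyDuplicated(s$name) && all(s$start == 0) &&
        all(s$end >= max(cc$times)) &&
        setequal(s$name, ctx[[1]]$inputs$name)
    }, logical(1)))
  if (stackable) {
    m <- length(ctx)
    sp_names <- network$species
    n_sp <- length(sp_names)
    clamped <- unique(ctx[[1]]$inputs$name)
    sim_st <- compile_sim_ctx(network, clamped, stacked = m)
    x0m <- matrix(rep(network$initial_state, each = m), m, n_sp)
    for (e in seq_len(m)) {
      s <- ctx[[e]]$inputs
      x0m[e, match(s$name, sp_names)] <- s$value
    }
    tt <- ctx[[1]]$times
    tt0 <- if (tt[1] > 0) c(0, tt) else tt
    e_idx <- match(data$experiment, exp_ids)
    pred_col <- e_idx + (match(data$species, sp_names) - 1L) * m
    pred_row <- match(data$time, tt)
    predict_obs_stacked <- function(k, keep_traj = FALSE) {
      sol <- run_lsoda(sim_st, as.vector(x0m), tt0, k, rtol, atol)
      if (is.null(sol) || nrow(sol) < length(tt0) || any(!is.finite(sol)))
        return(NULL)
      vals <- sol[match(tt, sol[, 1]), -1, drop = FALSE]
      vals[vals < 0] <- 0
      out <- list(pred = vals[cbind(pred_row, pred_col)])
      if (keep_traj)
        out$trajs <- lapply(seq_len(m), function(e)
          new_trajectory(tt, vals[, e + (seq_len(n_sp) - 1L) * m,
                                  drop = FALSE], sp_names))
      out
    }
  }

  predict_obs_loop <- function(k, keep_traj = FALSE) {
    pred <- numeric(nrow(data))
    trajs <- if (keep_traj) vector("list", length(ctx))
    for (e in seq_along(ctx)) {
      cc <- ctx[[e]]
      vals <- if (cc$linear) {
        v <- try(propagate_linear(network, k, cc$times), silent = TRUE)
        if (inherits(v, "try-error")) NULL else v
      }
      if (is.null(vals))
        vals <- tryCatch(
          integrate_ode(network, k, cc$times, cc$inputs, rtol, atol,
                        ctx = cc$sim),
          ptlasso_simulation_failure = function(err) NULL,
          error = function(err) NULL)
      if (is.null(vals) || any(!is.finite(vals))) return(NULL)
      vals[vals < 0] <- 0
      pred[cc$rows] <- vals[cbind(cc$it, cc$is)]
      if (keep_traj)
        trajs[[e]] <- new_trajectory(cc$times, vals, network$species)
    }
    if (keep_traj) list(pred = pred, trajs = trajs) else list(pred = pred)
  }
  predict_obs <- if (stackable) predict_obs_stacked else predict_obs_loop

  if (!is.null(grouped)) {
    if (!inherits(grouped, "grouped_spec"))
      stop("'grouped' must be a grouped_spec()")
    mods <- network_modules(network)
    if (is.null(mods))
      stop("specification error: grouped penalty needs module labels on ",
           "every reaction")
    modules <- unique(unname(mods))
    lam_names <- paste0("lambda_", modules)
    space <- parameter_space(
      c(lam_names, pars),
      lower = c(rep(grouped$lambda_lower, length(modules)),
                rep(grouped$lb, length(pars))),
      upper = c(rep(grouped$lambda_upper, length(modules)),
                rep(grouped$ub, length(pars))),
      prior = c(rep("laplace", length(modules)),
                rep("uniform", length(pars))),
      mu = grouped$mu, b = grouped$b)
    gidx <- match(mods, modules)
    n_mod <- length(modules)
    n_par <- length(pars)
  } else {
    if (is.null(space))
      space <- parameter_space(pars, prior = "laplace")
    if (!inherits(space, "parameter_space") ||
        !setequal(space$names, pars))
      stop("'space' must be a parameter_space over the network's parameters")
    # reorder to reaction order
    o <- match(pars, space$names)
    space <- parameter_space(pars, space$lower[o], space$upper[o],
                             space$prior[o], space$mu[o], space$b[o],
                             groups = space$groups[o])
  }
  lower <- unname(space$lower); upper <- unname(space$upper)
  is_lap <- space$prior == "laplace"
  lap_mu <- unname(space$mu[is_lap]); lap_b <- unname(space$b[is_lap])
  have_hard <- !is.null(constraints) && length(constraints$parsed) > 0
  have_soft <- !is.null(soft) && length(soft) > 0
  if (have_soft && !all(vapply(soft, inherits, logical(1),
                               "soft_constraint")))
    stop("'soft' must be a list of soft_constraint() objects")

  compose_theta <- if (is.null(grouped)) identity else function(theta) {
    theta[n_mod + seq_len(n_par)] + theta[gidx]
  }

  neg_loglik <- function(theta) {
    th_eff <- compose_theta(theta)
    res <- predict_obs(10^th_eff, keep_traj = have_soft)
    if (is.null(res)) return(Inf)
    nll <- sum((res$pred - data$mean)^2 / (2 * sigma_all^2))
    if (have_soft)
      for (sc in soft)
        nll <- nll + sc$weight * (sc$feature(res$trajs) - sc$target)^2
    nll
  }

  energy <- function(theta) {
    theta <- unname(theta)
    if (length(theta) != length(lower))
      stop("theta must have one entry per parameter")
    if (any(theta < lower) || any(theta > upper)) return(Inf)
    if (!is.null(grouped)) {
      kp <- theta[n_mod + seq_len(n_par)]
      # open interval: the boundary itself is excluded
      if (any(kp <= grouped$lb) || any(kp >= grouped$ub)) return(Inf)
    }
    if (have_hard &&
        !check_hard_constraints(stats::setNames(theta, space$names),
                                constraints)$pass)
      return(Inf)
    pen <- if (any(is_lap))
      sum(abs(theta[is_lap] - lap_mu) / lap_b) else 0
    nll <- neg_loglik(theta)
    if (!is.finite(nll)) return(Inf)
    nll + pen
  }

  structure(
    list(energy = energy,
         loglik = function(theta) -neg_loglik(unname(theta)),
         space = space, network = network, data = data,
         experiments = experiments, constraints = constraints, soft = soft,
         grouped = grouped, sigma = sigma_all,
         rtol = rtol, atol = atol,
         theta_names = pars, compose_theta = compose_theta,
         predict_obs = predict_obs),
    class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("Posterior energy model: %d sampled parameters, ",
                     "%d observation records, %d experiment(s)%s\n"),
              length(x$space$names), nrow(x$data), length(x$experiments),
              if (!is.null(x$grouped)) ", grouped penalty" else ""))
  invisible(x)
}

#' Evaluate the posterior energy at a parameter vector
#'
#' @param theta numeric vector in log10 space, ordered as
#'   `model$space$names` (names, if present, are ignored).
#' @param model an [energy_model()].
#' @return scalar energy; +Inf outside bounds, under violated hard
#'   constraints, or on simulation failure.
#' @export
posterior_energy <- function(theta, model) {
  stopifnot(inherits(model, "energy_model"))
  model$energy(theta)
}

#' Evaluate the grouped-penalty energy
#'
#' Composes the effective log10 rate constants theta'_i = k'_i +
#' lambda'_m(i) and evaluates the grouped energy
#' E = -log L + sum_m |lambda'_m - mu| / b + sum_i f(k'_i), with f zero
#' inside the open interval (lb, ub) and +Inf outside.
#'
#' @param lambda named or module-ordered numeric vector of module penalty
#'   parameters (log10).
#' @param kprime numeric vector of reaction-specific parameters (log10), in
#'   the network's reaction order.
#' @param model an [energy_model()] built with a [grouped_spec()].
#' @return scalar energy.
#' @export
grouped_energy <- function(lambda, kprime, model) {
  stopifnot(inherits(model, "energy_model"))
  if (is.null(model$grouped))
    stop("model was not built with a grouped penalty")
  model$energy(c(lambda, kprime))
}
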