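#' Fit and reduce a reaction network by tempered MCMC
#'
#' Calibrates a mass-action [reaction_network()] against observed time-course
#' data by parallel tempering MCMC in log10 parameter space and, with the
#' default Laplace (Lasso) prior, simultaneously shrinks dispensable rate
#' constants toward the prior location so the corresponding reactions can be
#' eliminated. `penalty = "none"` fits with plain box (uniform) priors —
#' ordinary Bayesian parameter estimation; `penalty = "grouped"` applies one
#' shared Laplace-penalized multiplier per reaction module (the network must
#' carry module labels), removing whole modules at a time.
#'
#' The posterior sample is the post-burn-in record of the beta = 1 chain,
#' one parameter vector per swap.
#'
#' @param network a [reaction_network()].
#' @param data observed data (columns species, time, mean, sd, optionally
#'   experiment), e.g. from [generate_observed()].
#' @param experiments named list of stimulus schedules per experiment level
#'   of `data`; `NULL` uses `network$inputs`.
#' @param penalty `"lasso"`, `"none"` or `"grouped"`.
#' @param mu,b Laplace prior location and width (log10 units) for
#'   `penalty = "lasso"`.
#' @param bounds length-2 log10 sampling box applied to every rate
#'   parameter.
#' @param grouped a [grouped_spec()], used when `penalty = "grouped"`.
#' @param constraints a [hard_constraints()] object or `NULL`.
#' @param soft list of [soft_constraint()] objects or `NULL`.
#' @param settings a [pt_settings()].
#' @param seed integer seed for chain initialization and sampling.
#' @param init `"prior-threshold"` (draw starts from the prior until the
#'   energy is below `init_threshold`) or `"warm-start"` (reuse `warm_start`
#'   vectors from an earlier run).
#' @param init_threshold energy threshold for prior-threshold initialization.
#' @param warm_start matrix of log10 start vectors for warm starts.
#' @param sd_floor minimum likelihood sigma (see [log_likelihood()]).
#' @param rtol,atol integrator tolerances.
#' @return an object of class `"ptlasso_fit"`; see [pt_samples()],
#'   [coef.ptlasso_fit()], [summary.ptlasso_fit()],
#'   [classify_parameters()].
#' @examples
#' \donttest{
#' net <- complete_unimolecular_network(3)
#' truth <- c(k_AB = 0.1, k_BC = 1)
#' obs <- generate_observed(net, truth, obs_times = seq(3.75, 30, 3.75),
#'                          noise_frac = 0.3, n_rep = 10, seed = 1)
#' fit <- ptlasso(net, obs, settings = pt_settings(n_swaps = 300,
#'                burn_in = 100), seed = 1)
#' coef(fit, scale = "linear")
#' }
#' @export
ptlasso <- function(network, data, experiments = NULL,
                    penalty = c("lasso", "none", "grouped"),
                    mu = -10, b = 1, bounds = c(-12, 3),
                    grouped = grouped_spec(),
                    constraints = NULL, soft = NULL,
                    settings = pt_settings(), seed = 1L,
                    init = c("prior-threshold", "warm-start"),
                    init_threshold = Inf, warm_start = NULL,
                    sd_floor = 0, rtol = 1e-6, atol = 1e-9) {
  penalty <- match.arg(penalty)
  init <- match.arg(init)
  pars <- network_params(network)
  if (penalty == "grouped") {
    model <- energy_model(network, data, experiments = experiments,
                          constraints = constraints, soft = soft,
                          grouped = grouped, sd_floor = sd_floor,
                          rtol = rtol, atol = atol)
  } else {
    space <- parameter_space(
      pars, lower = bounds[1], upper = bounds[2],
      prior = if (penalty == "lasso") "laplace" else "uniform",
      mu = mu, b = b)
    model <- energy_model(network, data, space, experiments = experiments,
                          constraints = constraints, soft = soft,
                          sd_floor = sd_floor, rtol = rtol, atol = atol)
  }
  t0 <- proc.time()[["elapsed"]]
  chains <- with_preserved_rng({
    set.seed(seed)
    init_chains(model$space, model$energy, settings$n_chains, mode = init,
                threshold = init_threshold, warm_start = warm_start)
  })
  chains <- lapply(chains, function(ch) {
    names(ch$theta) <- model$space$names
    ch
  })
  run <- run_pt(model$energy, chains, settings, seed = seed)
  fit <- structure(
    list(model = model, run = run, penalty = penalty,
         mu = if (penalty == "grouped") model$grouped$mu else mu,
         b = if (penalty == "grouped") model$grouped$b else b,
         seed = seed,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "ptlasso_fit")
  fit
}

with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Posterior sample matrix of a fit
#'
#' @param fit a `"ptlasso_fit"`.
#' @param include_burn_in keep burn-in rows.
#' @return matrix (samples x sampled parameters, log10 scale).
#' @export
fit_samples <- function(fit, include_burn_in = FALSE) {
  stopifnot(inherits(fit, "ptlasso_fit"))
  pt_samples(fit$run, include_burn_in = include_burn_in)
}

#' Log-likelihood trace of the posterior sample
#'
#' Recovers the per-sample log likelihood of the beta = 1 chain from the
#' recorded energies by subtracting the (analytically known) prior penalty,
#' so no re-simulation is needed. Only valid for fits without soft
#' constraints (their penalty is folded into the likelihood term).
#'
#' @param fit a `"ptlasso_fit"`.
#' @return numeric vector, one log likelihood per post-burn-in sample.
#' @export
loglik_trace <- function(fit) {
  stopifnot(inherits(fit, "ptlasso_fit"))
  E <- pt_energy(fit$run)
  sm <- fit_samples(fit)
  sp <- fit$model$space
  lap <- sp$prior == "laplace"
  pen <- if (any(lap))
    rowSums(abs(sweep(sm[, lap, drop = FALSE], 2, sp$mu[lap])) %*%
              diag(1 / sp$b[lap], sum(lap))) else 0
  -(E - pen)
}

#' Posterior mode of each sampled parameter
#'
#' Kernel-density mode of the marginal posterior of each parameter
#' (log10 scale), the summary used to read off recovered rate constants.
#'
#' @param samples matrix of posterior samples (log10) or a `"ptlasso_fit"`.
#' @return named numeric vector of marginal modes (log10).
#' @export
posterior_mode <- function(samples) {
  if (inherits(samples, "ptlasso_fit")) samples <- fit_samples(samples)
  apply(samples, 2, function(x) {
    if (stats::sd(x) < 1e-12) return(x[1])
    d <- stats::density(x)
    d$x[which.max(d$y)]
  })
}

#' @export
print.ptlasso_fit <- function(x, ...) {
  d <- dim(x$run$theta)
  cat(sprintf("ptlasso fit (penalty: %s)\n", x$penalty))
  cat(sprintf("  %d species / %d reactions; %d observation records\n",
              length(x$model$network$species),
              length(x$model$network$reactions), nrow(x$model$data)))
  cat(sprintf("  %d chains x %d swaps (burn-in %d) -> %d posterior samples\n",
              d[2], d[1], x$run$burn_in, d[1] - x$run$burn_in))
  if (x$penalty != "none")
    cat(sprintf("  Laplace prior: mu = %g, b = %g (log10)\n", x$mu, x$b))
  cat(sprintf("  mean posterior energy: %.2f | step acceptance (beta=1): %.3f\n",
              mean(pt_energy(x$run)), x$run$accept$step_rate[1]))
  invisible(x)
}

#' Posterior marginal modes of the rate constants
#'
#' @param object a `"ptlasso_fit"`.
#' @param scale `"log10"` (sampling scale) or `"linear"` (rate-constant
#'   units).
#' @param ... unused.
#' @return named numeric vector of marginal posterior modes.
#' @export
coef.ptlasso_fit <- function(object, scale = c("log10", "linear"), ...) {
  scale <- match.arg(scale)
  m <- posterior_mode(object)
  if (scale == "linear") 10^m else m
}

#' @export
logLik.ptlasso_fit <- function(object, ...) {
  ll <- mean(loglik_trace(object))
  structure(ll, df = length(object$model$space$names), class = "logLik")
}

#' Summarize a ptlasso fit
#'
#' Reports per-parameter marginal posterior summaries (mode, mean,
#' quantiles), acceptance rates, and — for Laplace-penalized fits — the
#' extraneous/necessary classification by prior confinement.
#'
#' @param object a `"ptlasso_fit"`.
#' @param c_boundary,mass_threshold see [classify_parameters()].
#' @param ... unused.
#' @return a `"summary.ptlasso_fit"` object.
#' @export
summary.ptlasso_fit <- function(object, c_boundary = 3,
                                mass_threshold = 0.9, ...) {
  sm <- fit_samples(object)
  tab <- data.frame(
    mode = posterior_mode(sm),
    mean = colMeans(sm),
    q025 = apply(sm, 2, stats::quantile, 0.025),
    q975 = apply(sm, 2, stats::quantile, 0.975))
  cls <- if (object$penalty != "none")
    classify_parameters(object, c_boundary = c_boundary,
                        mass_threshold = mass_threshold)
  structure(
    list(table = tab, classification = cls, penalty = object$penalty,
         n_samples = nrow(sm), accept = object$run$accept,
         mean_energy = mean(pt_energy(object$run)),
         mean_loglik = mean(loglik_trace(object))),
    class = "summary.ptlasso_fit")
}

#' @export
print.summary.ptlasso_fit <- function(x, ...) {
  cat(sprintf("ptlasso fit summary (penalty: %s, %d posterior samples)\n",
              x$penalty, x$n_samples))
  tab <- round(x$table, 3)
  if (!is.null(x$classification)) {
    cc <- x$classification$table
    tab$confined <- round(cc$confinement[match(rownames(tab), cc$parameter)], 3)
    tab$class <- cc$classification[match(rownames(tab), cc$parameter)]
  }
  print(tab)
  cat(sprintf("mean log likelihood: %.2f | mean energy: %.2f\n",
              x$mean_loglik, x$mean_energy))
  cat("step acceptance (beta=1 chain):",
      sprintf("%.3f", x$accept$step_rate[1]), "\n")
  invisible(x)
}

#' Predict trajectories from a fitted model
#'
#' Simulates the fitted network at the marginal posterior mode (default) or
#' for an ensemble of posterior draws.
#'
#' @param object a `"ptlasso_fit"`.
#' @param times time grid; defaults to 100 points spanning the observed
#'   window.
#' @param experiment experiment id (defaults to the first).
#' @param draws 0 for the posterior-mode trajectory, or the number of
#'   posterior draws for an ensemble.
#' @param ... unused.
#' @return a `"trajectory"` (draws = 0) or list of trajectories.
#' @export
predict.ptlasso_fit <- function(object, times = NULL, experiment = NULL,
                                draws = 0, ...) {
  model <- object$model
  if (is.null(experiment)) experiment <- names(model$experiments)[1]
  obs_t <- model$data$time[model$data$experiment == experiment]
  if (is.null(times))
    times <- seq(0, max(obs_t), length.out = 100)
  inputs <- model$experiments[[experiment]]
  sim1 <- function(theta_sampled) {
    k <- 10^model$compose_theta(unname(theta_sampled))
    names(k) <- model$theta_names
    simulate_network(model$network, k, times, inputs = inputs,
                     rtol = model$rtol, atol = model$atol)
  }
  if (draws == 0) return(sim1(posterior_mode(object)))
  sm <- fit_samples(object)
  idx <- round(seq(1, nrow(sm), length.out = draws))
  lapply(idx, function(i) sim1(sm[i, ]))
}

#' Posterior-predictive replicate datasets
#'
#' Draws parameter vectors from the posterior sample, simulates the network
#' at the observed (species, time) records and adds Gaussian measurement
#' noise with the fit's per-record sigma.
#'
#' @param object a `"ptlasso_fit"`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of data.frames shaped like the observed data.
#' @export
simulate.ptlasso_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_preserved_rng({
    if (!is.null(seed)) set.seed(seed)
    model <- object$model
    sm <- fit_samples(object)
    idx <- sample.int(nrow(sm), nsim, replace = nsim > nrow(sm))
    lapply(idx, function(i) {
      k <- 10^model$compose_theta(unname(sm[i, ]))
      pred <- model$predict_obs(k)$pred
      out <- model$data[c("experiment", "species", "time")]
      out$value <- pred + stats::rnorm(length(pred)) * model$sigma
      out
    })
  })
}

#' Standardized residuals at the posterior mode
#'
#' @param object a `"ptlasso_fit"`.
#' @param ... unused.
#' @return numeric vector: (observed mean - simulated) / sigma per record.
#' @export
residuals.ptlasso_fit <- function(object, ...) {
  model <- object$model
  k <- 10^model$compose_theta(unname(posterior_mode(object)))
  pred <- model$predict_obs(k)$pred
  (model$data$mean - pred) / model$sigma
}

#' Plot a ptlasso fit
#'
#' `type = "posterior"` draws the marginal posterior histogram of each
#' sampled parameter over its sampling range with the Laplace prior
#' boundaries marked; `type = "fit"` overlays posterior-draw trajectory
#' ensembles on the observed data; `type = "trace"` shows the beta = 1
#' energy trace.
#'
#' @param x a `"ptlasso_fit"`.
#' @param type plot type.
#' @param c_boundary half-width of the drawn prior boundary, in units of b.
#' @param draws ensemble size for `type = "fit"`.
#' @param ... passed to the underlying plot calls.
#' @return invisibly, `x`.
#' @export
plot.ptlasso_fit <- function(x, type = c("posterior", "fit", "trace"),
                             c_boundary = 3, draws = 30, ...) {
  type <- match.arg(type)
  sp <- x$model$space
  if (type == "posterior") {
    sm <- fit_samples(x)
    old <- graphics::par(mfrow = grDevices::n2mfrow(ncol(sm)),
                         mar = c(2.5, 2, 2, 0.5))
    on.exit(graphics::par(old))
    for (j in seq_len(ncol(sm))) {
      nm <- colnames(sm)[j]
      graphics::hist(sm[, j], breaks = 50,
                     xlim = c(sp$lower[nm], sp$upper[nm]),
                     main = nm, xlab = "", ylab = "", ...)
      if (sp$prior[nm] == "laplace")
        graphics::abline(v = sp$mu[nm] + c(-1, 1) * c_boundary * sp$b[nm],
                         col = "deeppink", lwd = 2)
    }
  } else if (type == "fit") {
    dat <- x$model$data
    exps <- unique(dat$experiment)
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(exps)),
                         mar = c(4, 4, 2, 0.5))
    on.exit(graphics::par(old))
    for (e in exps) {
      d <- dat[dat$experiment == e, ]
      trs <- predict(x, experiment = e, draws = draws)
      sp_obs <- unique(d$species)
      ylim <- range(0, d$mean + d$sd,
                    vapply(trs, function(tr)
                      max(tr$values[, sp_obs]), numeric(1)))
      graphics::plot(NA, xlim = c(0, max(d$time)), ylim = ylim,
                     xlab = "time (s)", ylab = "abundance (molecules)",
                     main = paste("experiment", e), ...)
      for (tr in trs)
        for (s in sp_obs)
          graphics::lines(tr$times, tr$values[, s],
                          col = grDevices::adjustcolor("steelblue", 0.25))
      graphics::arrows(d$time, d$mean - d$sd, d$time, d$mean + d$sd,
                       angle = 90, code = 3, length = 0.03)
      graphics::points(d$time, d$mean, pch = 19)
    }
  } else {
    graphics::plot(pt_energy(x$run), type = "l", xlab = "swap",
                   ylab = "energy (beta = 1 chain)", ...)
  }
  invisible(x)
}
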