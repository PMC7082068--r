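#' Parallel tempering sampler settings
#'
#' Configures the replica-exchange Metropolis-Hastings sampler: the ladder of
#' inverse temperatures beta (the chain with beta = 1 samples the true
#' posterior; hotter chains with beta < 1 accept unfavourable moves more
#' readily), the number of MH steps run between swap attempts, the total
#' number of swap attempts, and the burn-in adaptation of the per-chain
#' proposal scales toward the optimal acceptance rate 0.234. The default
#' ladder is geometric from 1 down to `beta_min` over `n_chains` chains.
#'
#' @param n_chains number of tempered chains.
#' @param beta_min smallest inverse temperature of the geometric ladder.
#' @param betas explicit ladder overriding the geometric default; must start
#'   at 1 and be strictly decreasing.
#' @param n_swaps total number of swap attempts ("swaps"); one sample per
#'   swap is recorded from every chain.
#' @param n_mcmc MH steps per chain between consecutive swap attempts.
#' @param burn_in number of initial swaps treated as burn-in; proposal-scale
#'   adaptation runs only there, and recorded burn-in samples are excluded
#'   from the posterior sample.
#' @param adapt enable burn-in adaptation of proposal scales.
#' @param target_accept step acceptance rate targeted by the adaptation.
#' @param eta multiplicative adaptation gain: after each burn-in swap,
#'   `scale <- scale * exp(eta * (rate - target_accept))`.
#' @param scale0 initial per-parameter Gaussian proposal sd (log10 units).
#' @return an object of class `"pt_settings"`.
#' @export
pt_settings <- function(n_chains = 6, beta_min = 0.05, betas = NULL,
                        n_swaps = 1000, n_mcmc = 25, burn_in = 200,
                        adapt = TRUE, target_accept = 0.234, eta = 0.5,
                        scale0 = 0.5) {
  if (is.null(betas)) {
    stopifnot(n_chains >= 1, beta_min > 0, beta_min <= 1)
    betas <- if (n_chains == 1) 1 else
      exp(seq(0, log(beta_min), length.out = n_chains))
    betas[1] <- 1
  }
  if (betas[1] != 1 || any(diff(betas) >= 0))
    stop("'betas' must start at 1 and be strictly decreasing")
  if (any(betas <= 0)) stop("'betas' must be positive")
  if (n_mcmc < 1) stop("'n_mcmc' must be >= 1")
  if (burn_in < 0 || burn_in >= n_swaps)
    stop("'burn_in' must be in [0, n_swaps)")
  structure(
    list(n_chains = length(betas), betas = betas, n_swaps = n_swaps,
         n_mcmc = n_mcmc, burn_in = burn_in, adapt = adapt,
         target_accept = target_accept, eta = eta, scale0 = scale0),
    class = "pt_settings")
}

#' Symmetric Gaussian proposal
#'
#' Perturbs every coordinate of a log10 parameter vector by an independent
#' Gaussian with per-coordinate sd `scale`. The proposal is symmetric, so it
#' drops out of the Metropolis acceptance ratio.
#'
#' @param theta numeric parameter vector (log10 scale).
#' @param scale positive per-coordinate proposal sd (recycled).
#' @return proposed parameter vector.
#' @export
propose <- function(theta, scale) {
  if (any(scale <= 0)) stop("proposal scales must be > 0")
  theta + stats::rnorm(length(theta)) * scale
}

#' One Metropolis-Hastings step
#'
#' Proposes a Gaussian perturbation and accepts it with probability
#' min(1, exp(-beta * dE)); on rejection the current state is kept. A
#' non-finite (NaN) energy from `energy_fn` is treated as +Inf (certain
#' rejection).
#'
#' @param theta current parameter vector (log10 scale).
#' @param E current energy, consistent with `theta`.
#' @param energy_fn function(theta) -> scalar energy.
#' @param beta inverse temperature in (0, 1].
#' @param scale proposal sd (see [propose()]).
#' @return list with `theta`, `E`, and logical `accepted`.
#' @export
mh_step <- function(theta, E, energy_fn, beta = 1, scale = 0.5) {
  prop <- propose(theta, scale)
  Ep <- energy_fn(prop)
  if (is.nan(Ep) || is.na(Ep)) Ep <- Inf
  dE <- Ep - E
  acc <- dE <= 0 || stats::runif(1) < exp(-beta * dE)
  if (acc) list(theta = prop, E = Ep, accepted = TRUE)
  else list(theta = theta, E = E, accepted = FALSE)
}

#' Attempt replica-exchange swaps between adjacent chains
#'
#' Walks the consecutive chain pairs in decreasing order of temperature
#' (hottest pair first) and exchanges the full parameter configurations of a
#' pair with probability min(1, exp(dbeta * dE)), where dbeta and dE are the
#' differences of the pair's inverse temperatures and energies taken in the
#' same order.
#'
#' @param theta matrix of chain states, one row per chain, row 1 the beta = 1
#'   chain, rows ordered by decreasing beta.
#' @param E numeric vector of chain energies.
#' @param betas decreasing inverse-temperature ladder.
#' @return list with the (possibly exchanged) `theta` and `E` and a logical
#'   vector `accepted`, one entry per adjacent pair, hottest pair first.
#' @export
attempt_swaps <- function(theta, E, betas) {
  n <- length(betas)
  stopifnot(nrow(theta) == n, length(E) == n, n >= 2)
  accepted <- logical(n - 1)
  for (i in seq(n, 2)) {
    delta <- (betas[i] - betas[i - 1]) * (E[i] - E[i - 1])
    if (delta >= 0 || stats::runif(1) < exp(delta)) {
      tmp <- theta[i, ]; theta[i, ] <- theta[i - 1, ]; theta[i - 1, ] <- tmp
      tmpE <- E[i]; E[i] <- E[i - 1]; E[i - 1] <- tmpE
      accepted[n - i + 1] <- TRUE
    }
  }
  list(theta = theta, E = E, accepted = accepted)
}

#' Burn-in adaptation of proposal scales
#'
#' Multiplicatively adjusts per-chain proposal scales toward the target step
#' acceptance rate: `scale * exp(eta * (rate - target))`. Rates above the
#' target grow the scale, rates below shrink it. Adaptation is only valid
#' during burn-in (varying the proposal during sampling would violate
#' detailed balance), so calling it for a swap index past the burn-in
#' horizon is an error.
#'
#' @param scales numeric vector (or matrix, chains x parameters) of proposal
#'   scales.
#' @param rates observed per-chain acceptance rates over the last adaptation
#'   window.
#' @param swap_index index of the current swap attempt.
#' @param burn_in burn-in horizon (number of swaps).
#' @param target target acceptance rate.
#' @param eta adaptation gain.
#' @return updated scales.
#' @export
adapt_burn_in <- function(scales, rates, swap_index, burn_in,
                          target = 0.234, eta = 0.5) {
  if (swap_index > burn_in)
    stop("contract violation: adaptation after burn-in is not allowed")
  f <- exp(eta * (rates - target))
  # clamp: proposals below 1e-3 decades are numerically idle, and beyond
  # ~2 decades per coordinate they are wasteful even for hot chains
  pmin(pmax(scales * f, 1e-3), 2)
}

#' Initialize tempered chains
#'
#' In `"prior-threshold"` mode each chain start is drawn from the prior
#' (uniformly in the box for uniform parameters, from the box-truncated
#' Laplace for penalized ones) until a vector with finite energy below
#' `threshold` is found. In `"warm-start"` mode the rows of `warm_start`
#' (recycled) are used and their energies recomputed.
#'
#' @param space a [parameter_space()].
#' @param energy_fn function(theta) -> scalar energy.
#' @param n_chains number of chains to seed.
#' @param mode `"prior-threshold"` or `"warm-start"`.
#' @param threshold energy threshold for accepting a prior draw.
#' @param warm_start numeric vector or matrix (rows recycled over chains) of
#'   log10 parameter vectors.
#' @param max_attempts attempts per chain before giving up.
#' @return list of chain states, each `list(theta, E)`.
#' @export
init_chains <- function(space, energy_fn, n_chains,
                        mode = c("prior-threshold", "warm-start"),
                        threshold = Inf, warm_start = NULL,
                        max_attempts = 1000) {
  mode <- match.arg(mode)
  npar <- length(space$names)
  if (mode == "warm-start") {
    if (is.null(warm_start)) stop("warm-start mode needs 'warm_start'")
    ws <- if (is.matrix(warm_start)) warm_start else
      matrix(warm_start, nrow = 1)
    if (ncol(ws) != npar) stop("warm_start has wrong dimension")
    return(lapply(seq_len(n_chains), function(c) {
      th <- ws[(c - 1) %% nrow(ws) + 1, ]
      list(theta = th, E = energy_fn(th))
    }))
  }
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be finite or +Inf")
  draw_prior <- function() {
    u <- stats::runif(npar)
    th <- numeric(npar)
    for (j in seq_len(npar)) {
      if (space$prior[j] == "laplace") {
        # inverse CDF of the Laplace truncated to [lower, upper]
        pl <- plaplace(space$lower[j], space$mu[j], space$b[j])
        pu <- plaplace(space$upper[j], space$mu[j], space$b[j])
        th[j] <- qlaplace(pl + u[j] * (pu - pl), space$mu[j], space$b[j])
      } else {
        th[j] <- space$lower[j] + u[j] * (space$upper[j] - space$lower[j])
      }
    }
    th
  }
  lapply(seq_len(n_chains), function(c) {
    best <- Inf
    for (a in seq_len(max_attempts)) {
      th <- draw_prior()
      E <- energy_fn(th)
      if (is.finite(E) && E < threshold)
        return(list(theta = th, E = E))
      if (is.finite(E) && E < best) best <- E
    }
    stop(sprintf(paste0("initialization failure: no prior draw with energy ",
                        "below %g in %d attempts (best energy found: %g)"),
                 threshold, max_attempts, best))
  })
}

plaplace <- function(q, mu, b) {
  ifelse(q < mu, 0.5 * exp((q - mu) / b), 1 - 0.5 * exp(-(q - mu) / b))
}

qlaplace <- function(p, mu, b) {
  ifelse(p < 0.5, mu + b * log(2 * p), mu - b * log(2 * (1 - p)))
}

#' Run the parallel tempering sampler
#'
#' Executes `n_swaps` rounds of `n_mcmc` Metropolis-Hastings steps per chain
#' followed by a replica-exchange swap pass, recording every chain's
#' parameter vector and energy at each swap. Each chain consumes its own
#' dedicated RNG stream and the swap pass a further stream (L'Ecuyer-CMRG),
#' so results are bit-reproducible for a given seed and independent of any
#' execution interleaving; chains are advanced serially here. During the
#' first `burn_in` swaps the per-chain proposal scales are adapted toward
#' the target acceptance rate and then frozen. With a single chain the
#' algorithm reduces to plain MH (no swap pass).
#'
#' @param energy_fn function(theta) -> scalar energy; non-finite values are
#'   treated as +Inf.
#' @param init list of chain states from [init_chains()] (or any list of
#'   `list(theta, E)`), one per chain, ordered by decreasing beta.
#' @param settings a [pt_settings()].
#' @param seed integer seed controlling all sampler randomness.
#' @return an object of class `"pt_run"`: list with `theta` (array,
#'   swaps x chains x parameters), `energy` (matrix, swaps x chains),
#'   `betas`, `burn_in`, `scales` (final per-chain proposal scales),
#'   `accept` (sampling-phase step tallies per chain and swap tallies per
#'   adjacent pair), `settings`, `seed`.
#' @export
run_pt <- function(energy_fn, init, settings = pt_settings(), seed = 1L) {
  stopifnot(inherits(settings, "pt_settings"))
  nc <- settings$n_chains
  if (length(init) != nc)
    stop("'init' must supply one chain state per chain (", nc, ")")
  betas <- settings$betas
  npar <- length(init[[1]]$theta)
  par_names <- names(init[[1]]$theta)

  # isolated RNG streams: one per chain plus one for the swap pass
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()))
  suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
  streams <- vector("list", nc + 1L)
  s <- get(".Random.seed", globalenv())
  for (i in seq_len(nc + 1L)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }

  theta <- do.call(rbind, lapply(init, `[[`, "theta"))
  E <- vapply(init, `[[`, numeric(1), "E")
  E[is.na(E)] <- Inf
  scales <- matrix(settings$scale0, nc, npar)
  th_hist <- array(NA_real_, c(settings$n_swaps, nc, npar),
                   dimnames = list(NULL, NULL, par_names))
  E_hist <- matrix(NA_real_, settings$n_swaps, nc)
  win_acc <- integer(nc)                 # acceptances since last adaptation
  samp_acc <- integer(nc)                # sampling-phase acceptances
  samp_steps <- integer(nc)
  swap_acc <- integer(max(nc - 1, 0))
  swap_att <- integer(max(nc - 1, 0))

  for (s_i in seq_len(settings$n_swaps)) {
    in_burn <- s_i <= settings$burn_in
    for (c_i in seq_len(nc)) {
      assign(".Random.seed", streams[[c_i]], globalenv())
      th <- theta[c_i, ]; Ec <- E[c_i]
      sc <- scales[c_i, ]; bet <- betas[c_i]
      acc <- 0L
      for (m in seq_len(settings$n_mcmc)) {
        prop <- th + stats::rnorm(npar) * sc
        Ep <- energy_fn(prop)
        if (is.na(Ep)) Ep <- Inf
        dE <- Ep - Ec
        if (dE <= 0 || stats::runif(1) < exp(-bet * dE)) {
          th <- prop; Ec <- Ep; acc <- acc + 1L
        }
      }
      theta[c_i, ] <- th; E[c_i] <- Ec
      win_acc[c_i] <- win_acc[c_i] + acc
      if (!in_burn) {
        samp_acc[c_i] <- samp_acc[c_i] + acc
        samp_steps[c_i] <- samp_steps[c_i] + settings$n_mcmc
      }
      streams[[c_i]] <- get(".Random.seed", globalenv())
    }
    if (nc >= 2) {
      assign(".Random.seed", streams[[nc + 1L]], globalenv())
      sw <- attempt_swaps(theta, E, betas)
      theta <- sw$theta; E <- sw$E
      if (!in_burn) {
        swap_att <- swap_att + 1L
        swap_acc <- swap_acc + as.integer(sw$accepted)
      }
      streams[[nc + 1L]] <- get(".Random.seed", globalenv())
    }
    th_hist[s_i, , ] <- theta
    E_hist[s_i, ] <- E
    if (settings$adapt && in_burn) {
      rates <- win_acc / settings$n_mcmc
      scales <- adapt_burn_in(scales, rates, s_i, settings$burn_in,
                              settings$target_accept, settings$eta)
    }
    win_acc[] <- 0L
  }

  structure(
    list(theta = th_hist, energy = E_hist, betas = betas,
         burn_in = settings$burn_in, scales = scales,
         accept = list(
           step_accepted = samp_acc, step_attempted = samp_steps,
           step_rate = ifelse(samp_steps > 0, samp_acc / samp_steps, NA_real_),
           swap_accepted = swap_acc, swap_attempted = swap_att,
           swap_rate = ifelse(swap_att > 0, swap_acc / swap_att, NA_real_)),
         settings = settings, seed = seed, par_names = par_names),
    class = "pt_run")
}

#' @export
print.pt_run <- function(x, ...) {
  d <- dim(x$theta)
  cat(sprintf(paste0("Parallel tempering run: %d swaps x %d chains x %d ",
                     "parameters (burn-in %d)\n"), d[1], d[2], d[3],
              x$burn_in))
  cat("Sampling-phase step acceptance per chain:",
      paste(sprintf("%.3f", x$accept$step_rate), collapse = " "), "\n")
  if (d[2] >= 2)
    cat("Swap acceptance per adjacent pair (hottest first):",
        paste(sprintf("%.3f", x$accept$swap_rate), collapse = " "), "\n")
  invisible(x)
}

#' Posterior samples from a PT run
#'
#' Returns the post-burn-in parameter vectors recorded from the lowest
#' temperature (beta = 1) chain, one row per swap: the posterior sample.
#'
#' @param run a `"pt_run"`.
#' @param chain chain index (1 = the beta = 1 chain).
#' @param include_burn_in keep the burn-in rows too.
#' @return matrix (samples x parameters, log10 scale).
#' @export
pt_samples <- function(run, chain = 1L, include_burn_in = FALSE) {
  stopifnot(inherits(run, "pt_run"))
  rows <- if (include_burn_in) seq_len(dim(run$theta)[1]) else
    seq(run$burn_in + 1L, dim(run$theta)[1])
  m <- run$theta[rows, chain, , drop = FALSE]
  out <- matrix(m, nrow = length(rows),
                dimnames = list(NULL, run$par_names))
  out
}

#' Post-burn-in energy trace of a chain
#'
#' @inheritParams pt_samples
#' @return numeric vector of energies, one per post-burn-in swap.
#' @export
pt_energy <- function(run, chain = 1L, include_burn_in = FALSE) {
  stopifnot(inherits(run, "pt_run"))
  rows <- if (include_burn_in) seq_len(nrow(run$energy)) else
    seq(run$burn_in + 1L, nrow(run$energy))
  run$energy[rows, chain]
}
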