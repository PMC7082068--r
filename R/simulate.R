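#' Simulate the mass-action ODE dynamics of a network
#'
#' Integrates the deterministic mass-action rate equations of a
#' [reaction_network()] at a given set of rate constants and returns species
#' abundances on the requested time grid. Integration is stiff-capable
#' (deSolve's lsoda, rtol 1e-6 / atol 1e-9 by default): tempered MCMC chains
#' routinely visit stiff corners of parameter space. Piecewise-constant
#' stimulus inputs are handled exactly by restarting the integration at every
#' schedule discontinuity. For networks consisting solely of first-order
#' conversion reactions (no modifiers, no inputs) the linear system is
#' propagated exactly through its eigendecomposition, falling back to the
#' numerical integrator when the eigenbasis is ill-conditioned.
#'
#' Small negative integrator slop is clipped to 0 before the trajectory is
#' returned (abundances are physical). A non-finite state aborts the
#' simulation with a condition of class `"ptlasso_simulation_failure"`
#' carrying the offending parameter vector; the sampler maps this condition
#' to infinite energy rather than crashing.
#'
#' @param network a [reaction_network()].
#' @param params named numeric vector of rate constants in linear space,
#'   covering every rate parameter of the network.
#' @param times strictly increasing numeric time grid (s), `times[1] >= 0`.
#'   The state is defined at t = 0; integration always starts there.
#' @param inputs stimulus schedule overriding `network$inputs` (see
#'   [reaction_network()]); `NULL` for none.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @return an object of class `"trajectory"`: list with elements `times`
#'   (the requested grid) and `values` (matrix, times x species).
#' @examples
#' net <- complete_unimolecular_network(3)
#' k <- setNames(rep(1e-12, 6), network_params(net))
#' k[c("k_AB", "k_BC")] <- c(0.1, 1)
#' tr <- simulate_network(net, k, times = seq(0, 30, length.out = 7))
#' tr$values[, "B"]
#' @export
simulate_network <- function(network, params, times,
                             inputs = network$inputs,
                             rtol = 1e-6, atol = 1e-9, .rhs = NULL) {
  pars <- network_params(network)
  if (is.null(names(params)) || !all(pars %in% names(params)))
    stop("'params' must be named and cover every rate parameter; missing: ",
         paste(setdiff(pars, names(params)), collapse = ", "))
  k <- unname(params[pars])
  if (!is.numeric(times) || length(times) < 1L || any(diff(times) <= 0) ||
      times[1] < 0)
    stop("'times' must be strictly increasing with times[1] >= 0")
  inputs <- validate_schedule(inputs, network$species)
  if (is.null(inputs) && is_linear_conversion(network)) {
    vals <- try(propagate_linear(network, k, times), silent = TRUE)
    if (!inherits(vals, "try-error") && all(is.finite(vals)))
      return(new_trajectory(times, vals, network$species))
    # fall through to the numerical integrator
  }
  vals <- integrate_ode(network, k, times, inputs, rtol, atol, rhs = .rhs)
  new_trajectory(times, vals, network$species)
}

new_trajectory <- function(times, values, species) {
  values[values < 0] <- 0
  dimnames(values) <- list(NULL, species)
  structure(list(times = times, values = values), class = "trajectory")
}

simulation_failure <- function(params, message = "ODE integration failed") {
  structure(
    class = c("ptlasso_simulation_failure", "error", "condition"),
    list(message = message, call = sys.call(-1), params = params))
}

is_linear_conversion <- function(network) {
  all(vapply(network$reactions, function(r)
    length(r$reactants) == 1L && r$reactants[[1]] == 1L &&
      length(r$modifiers) == 0L, logical(1)))
}

# exact solution of dx/dt = M x via eigendecomposition
propagate_linear <- function(network, k, times) {
  sp <- network$species
  n <- length(sp)
  M <- matrix(0, n, n, dimnames = list(sp, sp))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    from <- names(r$reactants)
    M[from, from] <- M[from, from] - k[j]
    for (p in names(r$products))
      M[p, from] <- M[p, from] + r$products[[p]] * k[j]
  }
  eg <- eigen(M)
  w <- solve(eg$vectors, network$initial_state)
  # x(t) = V diag(exp(lambda t)) V^-1 x0
  out <- eg$vectors %*% (w * exp(outer(eg$values, times)))
  if (is.complex(out)) {
    if (max(abs(Im(out))) > 1e-6 * max(1, max(abs(Re(out)))))
      stop("ill-conditioned eigenbasis")
    out <- Re(out)
  }
  t(out)
}

# Build a mass-action derivative function for the network once; the returned
# closure is function(t, x, k) so the same compiled context serves every
# parameter vector visited by the sampler. Derivatives of clamped (input)
# species are forced to 0. With stacked = m > 1, the generated function
# instead propagates m independent replicates of the system at once (state
# laid out as an m x n_species matrix), which lets a multi-experiment
# likelihood share a single integrator call.
compile_mass_action <- function(network, clamped = character(),
                                stacked = 0L) {
  sp <- network$species
  n <- length(sp)
  xi <- if (stacked > 0L) function(i) sprintf("x[, %d]", i)
  else function(i) sprintf("x[%d]", i)
  rate_txt <- vapply(seq_along(network$reactions), function(j) {
    r <- network$reactions[[j]]
    fac <- character()
    for (nm in names(r$reactants)) {
      i <- match(nm, sp); e <- r$reactants[[nm]]
      fac <- c(fac, if (e == 1L) xi(i) else sprintf("%s^%d", xi(i), e))
    }
    for (nm in r$modifiers) fac <- c(fac, xi(match(nm, sp)))
    if (stacked > 0L && !length(fac)) fac <- "one"
    paste(c(sprintf("k[%d]", j), fac), collapse = "*")
  }, character(1))
  terms <- rep(list(character()), n)
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (nm in names(r$reactants)) {
      i <- match(nm, sp); s <- r$reactants[[nm]]
      terms[[i]] <- c(terms[[i]], sprintf("-%s", if (s == 1L) paste0("r", j)
                                          else sprintf("%d*r%d", s, j)))
    }
    for (nm in names(r$products)) {
      i <- match(nm, sp); s <- r$products[[nm]]
      terms[[i]] <- c(terms[[i]], sprintf("+%s", if (s == 1L) paste0("r", j)
                                          else sprintf("%d*r%d", s, j)))
    }
  }
  idx_clamped <- match(clamped, sp)
  zero <- if (stacked > 0L) sprintf("numeric(%d)", stacked) else "0"
  dx <- vapply(seq_len(n), function(i) {
    if (i %in% idx_clamped || !length(terms[[i]])) zero
    else if (stacked > 0L)
      paste0("one * 0 ", paste(terms[[i]], collapse = " "))
    else paste(terms[[i]], collapse = " ")
  }, character(1))
  pre <- if (stacked > 0L)
    sprintf(" x <- matrix(pmax(x, 0), %d)\n one <- rep(1, %d)\n",
            stacked, stacked)
  else " x <- pmax(x, 0)\n"
  body_txt <- paste0(
    "function(t, x, k) {\n", pre, " ",
    paste(sprintf("r%d <- %s", seq_along(rate_txt), rate_txt),
          collapse = "\n "),
    "\n list(c(", paste(dx, collapse = ", "), "))\n}")
  eval(parse(text = body_txt)[[1]], envir = baseenv())
}

.ptl_env <- new.env(parent = emptyenv())

# Integer encoding of a network's mass-action structure for the compiled
# derivative routine: per-reaction species factors (index, exponent) and
# sparse stoichiometry triplets (clamped species excluded). Indices are
# 0-based. `stacked` > 1 requests simultaneous propagation of that many
# independent replicas (multi-experiment likelihoods).
network_tables <- function(network, clamped = character(), stacked = 1L) {
  sp <- network$species
  fsp <- integer(); fex <- integer(); foff <- 0L
  tsp <- integer(); trx <- integer(); tcoef <- numeric()
  idx_clamped <- match(clamped, sp)
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (nm in names(r$reactants)) {
      fsp <- c(fsp, match(nm, sp) - 1L)
      fex <- c(fex, r$reactants[[nm]])
    }
    for (nm in r$modifiers) {
      fsp <- c(fsp, match(nm, sp) - 1L)
      fex <- c(fex, 1L)
    }
    foff <- c(foff, length(fsp))
    net_change <- stats::setNames(numeric(length(sp)), sp)
    for (nm in names(r$reactants))
      net_change[nm] <- net_change[nm] - r$reactants[[nm]]
    for (nm in names(r$products))
      net_change[nm] <- net_change[nm] + r$products[[nm]]
    if (length(idx_clamped)) net_change[idx_clamped] <- 0
    nz <- which(net_change != 0)
    tsp <- c(tsp, nz - 1L)
    trx <- c(trx, rep(j - 1L, length(nz)))
    tcoef <- c(tcoef, unname(net_change[nz]))
  }
  list(dims = as.integer(c(length(sp), stacked, length(network$reactions),
                           length(fsp), length(tsp))),
       fsp = as.integer(fsp), fex = as.integer(fex),
       foff = as.integer(foff), tsp = as.integer(tsp),
       trx = as.integer(trx), tcoef = as.double(tcoef))
}

# Simulation context: compiled derivative tables when the package DLL is
# loaded (the normal case), generated R closure otherwise.
compile_sim_ctx <- function(network, clamped = character(), stacked = 0L) {
  if (is.loaded("ptl_set_network", PACKAGE = "ptlasso"))
    list(kind = "c",
         tables = network_tables(network, clamped, max(1L, stacked)))
  else
    list(kind = "r", rhs = compile_mass_action(network, clamped, stacked))
}

run_lsoda <- function(ctx, y, times, k, rtol, atol) {
  if (ctx$kind == "c") {
    tb <- ctx$tables
    .C("ptl_set_network", tb$dims, tb$fsp, tb$fex, tb$foff, tb$tsp,
       tb$trx, tb$tcoef, PACKAGE = "ptlasso")
    quiet_lsoda(y = y, times = times, func = "ptl_derivs", parms = k,
                dllname = "ptlasso", initfunc = "ptl_initparms",
                rtol = rtol, atol = atol)
  } else {
    quiet_lsoda(y = y, times = times, func = ctx$rhs, parms = k,
                rtol = rtol, atol = atol)
  }
}

# lsoda wrapped to (a) return NULL instead of erroring or warning, and
# (b) swallow the solver's Fortran diagnostics, which otherwise flood the
# console whenever a tempered chain proposes a pathological parameter
# vector. A vector whose integration needs more than `maxsteps` internal
# steps (typical well-posed problems here need a few dozen, and even
# strongly stiff but well-posed corners stay under ~100) is treated as
# failed; the caller maps that to infinite energy.
quiet_lsoda <- function(..., maxsteps = 500) {
  con <- .ptl_env$null_con
  if (is.null(con) || !isOpen(con)) {
    con <- file(nullfile(), open = "wt")
    .ptl_env$null_con <- con
  }
  sink(con)
  on.exit(sink())
  tryCatch(deSolve::lsoda(..., maxsteps = maxsteps),
           error = function(e) NULL, warning = function(w) NULL)
}

integrate_ode <- function(network, k, times, inputs, rtol, atol,
                          rhs = NULL, ctx = NULL) {
  sp <- network$species
  n <- length(sp)
  clamped <- if (is.null(inputs)) character() else unique(inputs$name)
  idx_clamped <- match(clamped, sp)
  if (!is.null(rhs)) ctx <- list(kind = "r", rhs = rhs)
  if (is.null(ctx)) ctx <- compile_sim_ctx(network, clamped)
  # segment the integration at stimulus discontinuities
  tmax <- max(times)
  breaks <- 0
  if (!is.null(inputs))
    breaks <- sort(unique(c(0, inputs$start, inputs$end)))
  breaks <- c(breaks[breaks < tmax], tmax)
  full <- sort(unique(c(times, breaks)))
  x <- network$initial_state
  out <- matrix(NA_real_, length(full), n)
  if (full[1] == 0) out[1, ] <- x
  for (s in seq_len(length(breaks) - 1L)) {
    a <- breaks[s]; b <- breaks[s + 1L]
    if (length(idx_clamped))
      x[idx_clamped] <- vapply(clamped, function(nm) {
        act <- inputs$name == nm & inputs$start <= a & inputs$end > a
        if (any(act)) sum(inputs$value[act]) else 0
      }, numeric(1))
    seg <- full[full >= a & full <= b]
    tt <- unique(c(a, seg, b))
    sol <- run_lsoda(ctx, x, tt, k, rtol, atol)
    if (is.null(sol) || any(!is.finite(sol)) || nrow(sol) < length(tt))
      stop(simulation_failure(stats::setNames(k, network_params(network))))
    keep <- match(seg, sol[, 1])
    out[match(seg, full), ] <- sol[keep, -1, drop = FALSE]
    x <- sol[nrow(sol), -1]
  }
  res <- out[match(times, full), , drop = FALSE]
  if (any(!is.finite(res)))
    stop(simulation_failure(stats::setNames(k, network_params(network))))
  res
}

#' Look up trajectory values for given species and times
#'
#' @param traj a `"trajectory"` from [simulate_network()].
#' @param species species name(s).
#' @param times time points; must match the trajectory grid to within 1e-8.
#' @return numeric vector (recycled over species/time pairs).
#' @export
trajectory_value <- function(traj, species, times) {
  it <- vapply(times, function(t) {
    j <- which(abs(traj$times - t) < 1e-8)
    if (!length(j)) NA_integer_ else j[1]
  }, integer(1))
  if (anyNA(it))
    stop("requested time not on the trajectory grid: ",
         paste(times[is.na(it)], collapse = ", "))
  is <- match(species, colnames(traj$values))
  if (anyNA(is))
    stop("unknown species: ", paste(species[is.na(is)], collapse = ", "))
  traj$values[cbind(it, is)]
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(
    time = rep(x$times, times = ncol(x$values)),
    species = rep(colnames(x$values), each = length(x$times)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points x %d species (t in [%g, %g] s)\n",
              length(x$times), ncol(x$values), min(x$times), max(x$times)))
  invisible(x)
}

#' Write a trajectory as tidy TSV
#'
#' Columns: time, species, value.
#'
#' @param traj a `"trajectory"`.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
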