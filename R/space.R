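#' Define the sampled parameter space
#'
#' All sampling, bounds and priors operate in log10 space: rate constants
#' span many decades and the field's conventional axes and its 1e-10
#' "proxy for zero" are decimal. Each parameter carries a (lower, upper)
#' log10 sampling box, treated as a uniform prior (0 inside, +Inf outside),
#' and optionally a Laplace (Lasso) shrinkage prior with location `mu` and
#' width `b`, both in log10 units. Laplace-penalized parameters still respect
#' the sampling box (the prior is the Laplace density restricted to the box,
#' unnormalized).
#'
#' @param names character vector of parameter names.
#' @param lower,upper log10 bounds, recycled across parameters.
#' @param prior `"uniform"` or `"laplace"`, recycled.
#' @param mu,b Laplace location and width in log10 units, recycled.
#' @param groups optional module labels (named by parameter or recycled) used
#'   by the grouped penalty.
#' @return an object of class `"parameter_space"`.
#' @export
parameter_space <- function(names, lower = -12, upper = 3,
                            prior = "uniform", mu = -10, b = 1,
                            groups = NULL) {
  n <- length(names)
  if (!is.character(names) || n < 1L || anyDuplicated(names))
    stop("'names' must be unique parameter names")
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower >= upper))
    stop("every parameter needs lower < upper")
  prior <- rep_len(prior, n)
  if (!all(prior %in% c("uniform", "laplace")))
    stop("prior must be 'uniform' or 'laplace'")
  mu <- rep_len(mu, n); b <- rep_len(b, n)
  if (any(b[prior == "laplace"] <= 0))
    stop("invalid hyperparameter: Laplace width b must be > 0")
  if (!is.null(groups)) {
    groups <- if (!is.null(names(groups))) {
      if (!all(names %in% names(groups)))
        stop("'groups' must cover every parameter")
      groups[names]
    } else rep_len(groups, n)
  }
  structure(
    list(names = names, lower = stats::setNames(lower, names),
         upper = stats::setNames(upper, names),
         prior = stats::setNames(prior, names),
         mu = stats::setNames(mu, names), b = stats::setNames(b, names),
         groups = if (is.null(groups)) NULL else
           stats::setNames(as.character(groups), names)),
    class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("Parameter space: %d parameters (log10 scale)\n",
              length(x$names)))
  df <- data.frame(lower = x$lower, upper = x$upper, prior = x$prior)
  df$mu <- ifelse(x$prior == "laplace", x$mu, NA)
  df$b <- ifelse(x$prior == "laplace", x$b, NA)
  if (!is.null(x$groups)) df$module <- x$groups
  print(df)
  invisible(x)
}

#' Unnormalized Laplace log prior
#'
#' Returns -|theta - mu| / b, the log of the Laplace density with the
#' constant -log(2b) dropped (constants cancel in Metropolis ratios).
#'
#' @param theta parameter value(s), log10 scale.
#' @param mu prior location (log10).
#' @param b prior width (log10 units), > 0.
#' @return numeric vector of unnormalized log-prior values.
#' @examples
#' laplace_log_prior(-1, mu = -10, b = 1)  # -9
#' @export
laplace_log_prior <- function(theta, mu, b) {
  if (any(b <= 0)) stop("invalid hyperparameter: Laplace width b must be > 0")
  -abs(theta - mu) / b
}

#' Settings for the grouped (module-level) penalty
#'
#' Under the grouped penalty every reaction i in module m has log10 rate
#' constant theta'_i = k'_i + lambda'_m: a module-shared penalty parameter
#' lambda'_m, carrying the Laplace prior, plus a reaction-specific parameter
#' k'_i confined to the open box (LB, UB) (infinite energy outside).
#' Shrinking lambda'_m to its prior location mu removes the whole module,
#' because the largest attainable rate, about 10^(UB + mu), is chosen to be
#' below the floor that affects the dynamics. Defaults mu = -25, LB = -5,
#' UB = 10 satisfy this for b = 2.
#'
#' @param mu,b Laplace location and width for the module penalty parameters
#'   (log10 units).
#' @param lb,ub open-interval box for the reaction-specific parameters
#'   (log10), recycled per reaction.
#' @param lambda_lower,lambda_upper sampling bounds for the penalty
#'   parameters (log10).
#' @return an object of class `"grouped_spec"`.
#' @export
grouped_spec <- function(mu = -25, b = 2, lb = -5, ub = 10,
                         lambda_lower = -35, lambda_upper = 6) {
  if (b <= 0) stop("invalid hyperparameter: Laplace width b must be > 0")
  if (any(lb >= ub)) stop("need lb < ub")
  structure(list(mu = mu, b = b, lb = lb, ub = ub,
                 lambda_lower = lambda_lower, lambda_upper = lambda_upper),
            class = "grouped_spec")
}

#' Hard parameter constraints
#'
#' Hard constraints are strict inequalities over named parameters, evaluated
#' in log10 space, that cannot be violated: any violation gives the
#' parameter vector infinite energy. Constraints are written as strings such
#' as `"k_a > k_b"` or `"k_a < -2"`.
#'
#' @param exprs character vector of inequality strings using `<` or `>`.
#' @return an object of class `"hard_constraints"`.
#' @export
hard_constraints <- function(exprs) {
  if (!is.character(exprs)) stop("'exprs' must be character")
  parsed <- lapply(exprs, function(s) {
    e <- tryCatch(parse(text = s)[[1]], error = function(err) NULL)
    if (is.null(e) || !is.call(e) ||
        !as.character(e[[1]]) %in% c("<", ">", "<=", ">="))
      stop("cannot parse constraint (expected an inequality): ", s)
    e
  })
  structure(list(exprs = exprs, parsed = parsed),
            class = "hard_constraints")
}

#' Check hard constraints at a parameter vector
#'
#' @param theta named numeric vector (log10 scale).
#' @param constraints a [hard_constraints()] object (or `NULL` for none).
#' @return list with elements `pass` (logical) and `violated` (character
#'   vector of violated constraint strings).
#' @examples
#' cs <- hard_constraints("k_a > k_b")
#' check_hard_constraints(c(k_a = 1, k_b = 0), cs)$pass   # TRUE
#' check_hard_constraints(c(k_a = 0, k_b = 0), cs)$pass   # FALSE (strict)
#' @export
check_hard_constraints <- function(theta, constraints) {
  if (is.null(constraints) || !length(constraints$parsed))
    return(list(pass = TRUE, violated = character()))
  env <- as.list(theta)
  ok <- vapply(constraints$parsed, function(e) {
    v <- tryCatch(eval(e, env), error = function(err)
      stop("constraint references unknown parameter: ", deparse(e)))
    isTRUE(v)
  }, logical(1))
  list(pass = all(ok), violated = constraints$exprs[!ok])
}

#' Soft constraint: weighted quadratic penalty on a trajectory feature
#'
#' Soft constraints can be violated at a finite energy cost. The penalty
#' added to the energy is `weight * (feature(trajectories) - target)^2`,
#' where `feature` is a user function receiving the list of simulated
#' trajectories (one per experiment). A typical use is penalizing terminal
#' deviation from baseline to require transient responses.
#'
#' @param feature function(list of trajectories) -> single numeric.
#' @param target target feature value.
#' @param weight penalty weight (>= 0).
#' @return an object of class `"soft_constraint"`.
#' @export
soft_constraint <- function(feature, target = 0, weight = 1) {
  stopifnot(is.function(feature), weight >= 0)
  structure(list(feature = feature, target = target, weight = weight),
            class = "soft_constraint")
}
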