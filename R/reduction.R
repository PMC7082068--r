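#' Classify parameters as extraneous or necessary by prior confinement
#'
#' A Laplace-penalized parameter whose marginal posterior stays confined
#' within the prior boundaries carries no information beyond the shrinkage
#' prior: its reaction is extraneous (dispensable for fitting the data). A
#' posterior that escapes the prior is necessary. The boundary interval is
#' `[mu - c_boundary * b, mu + c_boundary * b]` (the default half-width of
#' 3 b covers 1 - exp(-3), about 95%, of the Laplace mass) and a parameter
#' is called extraneous when at least `mass_threshold` of its posterior
#' samples fall inside. The default mass threshold of 0.9 sits deliberately
#' below the ~0.95 boundary mass: a posterior that exactly equals the prior
#' then clears the threshold with margin instead of flipping on sampling
#' noise, while necessary parameters in practice have confinement far below
#' it. Parameters without a Laplace prior are skipped with a notice.
#'
#' @param x a `"ptlasso_fit"`, or a matrix of posterior samples (log10,
#'   named columns).
#' @param mu,b Laplace prior location(s) and width(s), recycled over
#'   columns; taken from the fit's parameter space when `x` is a fit.
#' @param c_boundary boundary half-width in units of b.
#' @param mass_threshold posterior mass required for the extraneous call.
#' @return an object of class `"reduction_report"`: list with `table`
#'   (parameter, mu, b, confinement, classification), the boundary
#'   definition, and `extraneous`/`necessary` name vectors.
#' @export
classify_parameters <- function(x, mu = NULL, b = NULL, c_boundary = 3,
                                mass_threshold = 0.9) {
  if (inherits(x, "ptlasso_fit")) {
    sp <- x$model$space
    samples <- fit_samples(x)
    lap <- sp$prior == "laplace"
    skipped <- sp$names[!lap]
    if (length(skipped))
      message("skipping parameters without a Laplace prior: ",
              paste(skipped, collapse = ", "))
    samples <- samples[, lap, drop = FALSE]
    mu <- sp$mu[lap]; b <- sp$b[lap]
  } else {
    samples <- as.matrix(x)
    if (is.null(mu) || is.null(b))
      stop("supply 'mu' and 'b' when classifying a raw sample matrix")
    skipped <- character()
  }
  if (nrow(samples) == 0) stop("no posterior samples")
  p <- ncol(samples)
  mu <- rep_len(mu, p); b <- rep_len(b, p)
  confinement <- vapply(seq_len(p), function(j)
    mean(samples[, j] >= mu[j] - c_boundary * b[j] &
           samples[, j] <= mu[j] + c_boundary * b[j]), numeric(1))
  cls <- ifelse(confinement >= mass_threshold, "extraneous", "necessary")
  tab <- data.frame(parameter = colnames(samples), mu = mu, b = b,
                    confinement = confinement, classification = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(table = tab, c_boundary = c_boundary,
         mass_threshold = mass_threshold,
         boundary = "[mu - c*b, mu + c*b]",
         extraneous = tab$parameter[cls == "extraneous"],
         necessary = tab$parameter[cls == "necessary"],
         skipped = skipped),
    class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf(paste0("Reduction report (boundary %s, c = %g, ",
                     "mass threshold = %g)\n"),
              x$boundary, x$c_boundary, x$mass_threshold))
  tab <- x$table
  tab$confinement <- round(tab$confinement, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("extraneous: %s\nnecessary:  %s\n",
              paste(x$extraneous, collapse = ", "),
              paste(x$necessary, collapse = ", ")))
  invisible(x)
}

#' Census of active-parameter supports in a posterior sample
#'
#' Maps each posterior sample to its support — the set of parameters whose
#' log10 value exceeds the activity threshold — and aggregates identical
#' supports with their posterior frequencies. Mutually exclusive supports
#' reveal alternate reduced models that fit the data equally well. The
#' default threshold of -5 sits midway between the shrinkage target
#' (mu = -10) and the data-informed region, far above mu + 3b.
#'
#' @param samples matrix of posterior samples (log10) or a
#'   `"ptlasso_fit"`.
#' @param threshold activity threshold in log10 space.
#' @return an object of class `"support_census"`: data.frame-backed list
#'   with `table` (support string, frequency, count, descending) and
#'   `supports` (list of character vectors).
#' @export
extract_supports <- function(samples, threshold = -5) {
  if (inherits(samples, "ptlasso_fit")) samples <- fit_samples(samples)
  act <- samples > threshold
  keys <- apply(act, 1, function(r)
    paste(colnames(samples)[r], collapse = "+"))
  keys[keys == ""] <- "(empty)"
  tab <- sort(table(keys), decreasing = TRUE)
  out <- data.frame(support = names(tab),
                    count = as.integer(tab),
                    frequency = as.numeric(tab) / nrow(samples),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(table = out,
         supports = lapply(strsplit(out$support, "+", fixed = TRUE),
                           function(s) setdiff(s, "(empty)")),
         threshold = threshold, n_samples = nrow(samples)),
    class = "support_census")
}

#' @export
print.support_census <- function(x, ...) {
  cat(sprintf("Support census (threshold %g log10, %d samples)\n",
              x$threshold, x$n_samples))
  tab <- x$table
  tab$frequency <- round(tab$frequency, 4)
  print(utils::head(tab, 10), row.names = FALSE)
  if (nrow(tab) > 10) cat("...", nrow(tab) - 10, "more\n")
  invisible(x)
}

#' Elbow-rule selection of the Lasso width b
#'
#' Picks the smallest b (the strongest regularization) whose mean negative
#' log likelihood does not substantially exceed the unregularized (plain
#' PT) reference: the first b on the ascending grid with
#' `nll_mean <= ref_mean + tolerance`, the tolerance defaulting to one
#' reference standard deviation. If no b qualifies the largest b is
#' returned with a warning.
#'
#' @param b_grid ascending grid of candidate b values.
#' @param nll_mean per-b mean negative log likelihood of the PTLasso fits.
#' @param nll_sd per-b sd of the negative log likelihood (reported, not
#'   used by the rule).
#' @param ref_mean,ref_sd mean and sd of the negative log likelihood of the
#'   unregularized reference run.
#' @param tolerance acceptance slack; default `ref_sd`.
#' @return list with `b` (selected), `qualified` (logical per grid point)
#'   and the inputs.
#' @export
select_b <- function(b_grid, nll_mean, nll_sd = NULL, ref_mean, ref_sd,
                     tolerance = ref_sd) {
  if (!length(b_grid)) stop("specification error: empty b grid")
  if (is.unsorted(b_grid, strictly = TRUE))
    stop("'b_grid' must be sorted ascending")
  if (length(nll_mean) != length(b_grid))
    stop("'nll_mean' must match 'b_grid'")
  ok <- nll_mean <= ref_mean + tolerance
  b <- if (any(ok)) b_grid[which(ok)[1]] else {
    warning("no b on the grid preserves fit quality; returning largest b")
    b_grid[length(b_grid)]
  }
  list(b = b, qualified = ok, b_grid = b_grid, nll_mean = nll_mean,
       nll_sd = nll_sd, ref_mean = ref_mean, ref_sd = ref_sd,
       tolerance = tolerance)
}

#' Sweep the Lasso width b over a grid of PTLasso fits
#'
#' Runs one PTLasso fit per b plus one unregularized PT reference fit, and
#' applies the elbow rule of [select_b()] to the resulting negative
#' log-likelihood summaries.
#'
#' @param network,data,experiments as in [ptlasso()].
#' @param b_grid ascending grid of b values.
#' @param mu Laplace location.
#' @param settings a [pt_settings()] used for every fit.
#' @param seed base seed; fit i uses `seed + i`.
#' @param ... further arguments passed to [ptlasso()].
#' @return list with `selection` (from [select_b()]), `fits` (per-b), and
#'   `reference` (the PT fit).
#' @export
scan_b <- function(network, data, b_grid, experiments = NULL, mu = -10,
                   settings = pt_settings(), seed = 1L, ...) {
  if (!length(b_grid)) stop("specification error: empty b grid")
  ref <- ptlasso(network, data, experiments = experiments,
                 penalty = "none", settings = settings, seed = seed, ...)
  ref_nll <- -loglik_trace(ref)
  fits <- lapply(seq_along(b_grid), function(i)
    ptlasso(network, data, experiments = experiments, penalty = "lasso",
            mu = mu, b = b_grid[i], settings = settings,
            seed = seed + i, ...))
  nll <- vapply(fits, function(f) mean(-loglik_trace(f)), numeric(1))
  nll_sd <- vapply(fits, function(f) stats::sd(-loglik_trace(f)),
                   numeric(1))
  sel <- select_b(b_grid, nll, nll_sd, mean(ref_nll), stats::sd(ref_nll))
  list(selection = sel, fits = fits, reference = ref)
}

#' Stability of the reduction under perturbations of mu
#'
#' Re-runs the prior-confinement classification with the Laplace location
#' shifted by ±delta (the posterior sample is reused; only the boundary
#' moves) and reports which parameters change class — a borderline
#' parameter flipping under a small shift is flagged unstable.
#'
#' @param fit a `"ptlasso_fit"` with Laplace-penalized parameters.
#' @param delta perturbation of mu in log10 units (default 1).
#' @param c_boundary,mass_threshold see [classify_parameters()].
#' @return data.frame (parameter, class at mu - delta, mu, mu + delta,
#'   stable).
#' @export
sensitivity_mu <- function(fit, delta = 1, c_boundary = 3,
                           mass_threshold = 0.9) {
  stopifnot(inherits(fit, "ptlasso_fit"))
  sp <- fit$model$space
  lap <- sp$prior == "laplace"
  samples <- fit_samples(fit)[, lap, drop = FALSE]
  cls_at <- function(shift)
    classify_parameters(samples, mu = sp$mu[lap] + shift, b = sp$b[lap],
                        c_boundary = c_boundary,
                        mass_threshold = mass_threshold)$table$classification
  lo <- cls_at(-delta); mid <- cls_at(0); hi <- cls_at(delta)
  data.frame(parameter = colnames(samples),
             class_minus = lo, class_mu = mid, class_plus = hi,
             stable = lo == mid & mid == hi,
             stringsAsFactors = FALSE, row.names = NULL)
}
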