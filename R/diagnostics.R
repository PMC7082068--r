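#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Classical (non-split, non-rank-normalized) Gelman-Rubin convergence
#' statistic for one scalar parameter traced by m >= 2 chains of equal
#' length n: with W the mean within-chain variance and B/n the variance of
#' the chain means,
#' \deqn{PSRF^2 = \frac{m+1}{m}\,\frac{(n-1)W/n + B/n}{W} - \frac{n-1}{mn}.}
#' Values near 1 are consistent with the chains sampling the same
#' distribution; the conventional convergence standard used here is
#' PSRF < 1.2. For identical non-constant chains B = 0 and the statistic
#' equals sqrt((n-1)/n).
#'
#' @param chains list of equal-length numeric vectors (>= 2 chains), or a
#'   matrix with one chain per column.
#' @return scalar PSRF.
#' @export
psrf <- function(chains) {
  x <- as_chain_matrix(chains)
  n <- nrow(x); m <- ncol(x)
  if (n < 2) stop("chains must have length >= 2")
  W <- mean(apply(x, 2, stats::var))
  if (W == 0) stop("degenerate chain: zero within-chain variance")
  Bn <- stats::var(colMeans(x))          # B/n
  vhat <- (n - 1) / n * W + Bn
  sqrt((m + 1) / m * vhat / W - (n - 1) / (m * n))
}

as_chain_matrix <- function(chains) {
  if (is.matrix(chains)) x <- chains
  else {
    if (!is.list(chains)) stop("'chains' must be a list or matrix")
    len <- vapply(chains, length, integer(1))
    if (length(unique(len)) != 1)
      stop("specification error: chains must have equal length")
    x <- do.call(cbind, chains)
  }
  if (ncol(x) < 2) stop("need >= 2 chains")
  x
}

#' Multivariate potential scale reduction factor (Brooks-Gelman)
#'
#' Extends [psrf()] to parameter vectors by checking convergence of the
#' parameter covariation: with W the mean within-chain covariance matrix
#' and B/n the covariance of the chain means,
#' \deqn{MPSRF^2 = \frac{n-1}{n} + \frac{m+1}{m}\,
#'   \lambda_{max}(W^{-1}B/n).}
#' MPSRF is bounded below by the largest univariate PSRF over the
#' coordinates and reduces to it in one dimension.
#'
#' @param chains list of equal-dimension numeric matrices (samples x
#'   parameters), one per chain, >= 2 chains.
#' @return scalar MPSRF.
#' @export
mpsrf <- function(chains) {
  if (!is.list(chains) ||
      !all(vapply(chains, is.matrix, logical(1))))
    chains <- lapply(chains, as.matrix)
  dims <- vapply(chains, function(x) c(nrow(x), ncol(x)), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("specification error: chains must have identical dimensions")
  m <- length(chains)
  if (m < 2) stop("need >= 2 chains")
  n <- nrow(chains[[1]])
  if (n < 2) stop("chains must have length >= 2")
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  mu <- do.call(rbind, lapply(chains, colMeans))
  Bn <- stats::cov(mu)                   # B/n
  WB <- tryCatch(solve(W, Bn), error = function(e)
    stop("degenerate covariance: singular within-chain covariance"))
  lam <- max(Re(eigen(WB, only.values = TRUE)$values))
  sqrt((n - 1) / n + (m + 1) / m * lam)
}

#' Gate-and-combine parallel sample stores
#'
#' When a long chain of N swaps is replaced by M shorter parallel runs of
#' N/M swaps from the same start point, the M runs may be concatenated into
#' one sample only if they explored the same energy basin. The gate is the
#' univariate PSRF of the M post-burn-in energy traces: below `threshold`
#' the stores are combined; otherwise combination is refused and the PSRF
#' reported. A single store passes through with a warning (no PSRF is
#' computable).
#'
#' @param runs list of `"pt_run"` or `"ptlasso_fit"` objects with equal
#'   post-burn-in lengths.
#' @param threshold PSRF gate (default 1.2).
#' @return list with `passed`, `psrf_energy`, and (when passed) `samples`
#'   (row-bound posterior samples) and `energy` (concatenated traces).
#' @export
combine_chains <- function(runs, threshold = 1.2) {
  runs <- lapply(runs, function(r)
    if (inherits(r, "ptlasso_fit")) r$run else r)
  if (!all(vapply(runs, inherits, logical(1), "pt_run")))
    stop("'runs' must be pt_run or ptlasso_fit objects")
  energies <- lapply(runs, pt_energy)
  if (length(runs) == 1) {
    warning("single store: passing through without a PSRF gate")
    return(list(passed = TRUE, psrf_energy = NA_real_,
                samples = pt_samples(runs[[1]]), energy = energies[[1]]))
  }
  if (length(unique(lengths(energies))) != 1)
    stop("specification error: stores must have equal length")
  r_energy <- psrf(energies)
  if (r_energy < threshold)
    list(passed = TRUE, psrf_energy = r_energy,
         samples = do.call(rbind, lapply(runs, pt_samples)),
         energy = do.call(c, energies))
  else
    list(passed = FALSE, psrf_energy = r_energy)
}

#' Acceptance-rate report of a sampler run
#'
#' Sampling-phase step acceptance per chain (accepted / attempted MH steps)
#' and swap acceptance per adjacent temperature pair. Rates with zero
#' attempts are flagged as undefined (NA).
#'
#' @param run a `"pt_run"` or `"ptlasso_fit"`.
#' @return list with data.frames `steps` (chain, beta, accepted, attempted,
#'   rate) and `swaps` (pair, accepted, attempted, rate).
#' @export
acceptance_report <- function(run) {
  if (inherits(run, "ptlasso_fit")) run <- run$run
  stopifnot(inherits(run, "pt_run"))
  a <- run$accept
  nc <- length(run$betas)
  steps <- data.frame(
    chain = seq_len(nc), beta = run$betas,
    accepted = a$step_accepted, attempted = a$step_attempted,
    rate = ifelse(a$step_attempted > 0,
                  a$step_accepted / a$step_attempted, NA_real_))
  swaps <- if (nc >= 2) data.frame(
    pair = paste(seq(nc, 2), seq(nc - 1, 1), sep = "-"),
    accepted = a$swap_accepted, attempted = a$swap_attempted,
    rate = ifelse(a$swap_attempted > 0,
                  a$swap_accepted / a$swap_attempted, NA_real_))
  else data.frame(pair = character(), accepted = integer(),
                  attempted = integer(), rate = numeric())
  list(steps = steps, swaps = swaps)
}

#' Convergence diagnostics across independent runs
#'
#' Computes the per-parameter Gelman-Rubin PSRF and the multivariate MPSRF
#' from the beta = 1 posterior samples of two or more independently seeded
#' runs of the same fit, plus acceptance-rate summaries, and declares
#' convergence when the maximum univariate PSRF is below the threshold.
#'
#' @param fits list of >= 2 `"ptlasso_fit"` or `"pt_run"` objects.
#' @param threshold convergence threshold on max PSRF (default 1.2).
#' @return an object of class `"diagnostics_report"`.
#' @export
diagnostics_report <- function(fits, threshold = 1.2) {
  runs <- lapply(fits, function(r)
    if (inherits(r, "ptlasso_fit")) r$run else r)
  if (length(runs) < 2) stop("need >= 2 independent runs")
  samples <- lapply(runs, pt_samples)
  p <- ncol(samples[[1]])
  par_names <- colnames(samples[[1]])
  psrf_par <- vapply(seq_len(p), function(j)
    psrf(lapply(samples, function(s) s[, j])), numeric(1))
  names(psrf_par) <- par_names
  mp <- tryCatch(mpsrf(samples), error = function(e) NA_real_)
  structure(
    list(psrf = psrf_par, max_psrf = max(psrf_par), mpsrf = mp,
         threshold = threshold, converged = max(psrf_par) < threshold,
         acceptance = lapply(runs, acceptance_report)),
    class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Convergence diagnostics\n")
  print(round(x$psrf, 4))
  cat(sprintf("max PSRF: %.4f | MPSRF: %.4f | threshold: %g -> %s\n",
              x$max_psrf, x$mpsrf, x$threshold,
              if (x$converged) "consistent with convergence"
              else "NOT converged"))
  invisible(x)
}
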