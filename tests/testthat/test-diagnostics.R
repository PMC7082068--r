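# independent oracle implementations of the classical Gelman-Rubin
# statistics, written as plain sums so they cannot share code with the
# package's vectorized versions
psrf_oracle <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  means <- numeric(m); vars <- numeric(m)
  for (j in seq_len(m)) {
    mu <- sum(chains[[j]]) / n
    means[j] <- mu
    vars[j] <- sum((chains[[j]] - mu)^2) / (n - 1)
  }
  W <- sum(vars) / m
  grand <- sum(means) / m
  B <- n / (m - 1) * sum((means - grand)^2)
  vhat <- (n - 1) / n * W + B / n
  sqrt((m + 1) / m * vhat / W - (n - 1) / (m * n))
}

mpsrf_oracle <- function(chains) {
  m <- length(chains); n <- nrow(chains[[1]]); p <- ncol(chains[[1]])
  W <- matrix(0, p, p); means <- matrix(0, m, p)
  for (j in seq_len(m)) {
    mu <- colSums(chains[[j]]) / n
    means[j, ] <- mu
    cent <- sweep(chains[[j]], 2, mu)
    W <- W + t(cent) %*% cent / (n - 1)
  }
  W <- W / m
  grand <- colSums(means) / m
  Bn <- matrix(0, p, p)
  for (j in seq_len(m)) {
    d <- means[j, ] - grand
    Bn <- Bn + outer(d, d)
  }
  Bn <- Bn / (m - 1)
  lam <- max(Re(eigen(solve(W) %*% Bn, only.values = TRUE)$values))
  sqrt((n - 1) / n + (m + 1) / m * lam)
}

test_that("PSRF matches an independent oracle on random fixtures", {
  set.seed(42)
  for (i in 1:20) {
    m <- sample(2:5, 1); n <- sample(50:200, 1)
    shift <- runif(1, 0, 2)
    chains <- lapply(seq_len(m), function(j)
      rnorm(n, mean = j * shift, sd = runif(1, 0.5, 2)))
    expect_equal(psrf(chains), psrf_oracle(chains), tolerance = 1e-8)
  }
})

test_that("PSRF has its analytic value for identical and separated chains", {
  x <- rnorm(100)
  expect_equal(psrf(list(x, x)), sqrt(99 / 100), tolerance = 1e-12)
  set.seed(1)
  far <- list(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(psrf(far), 1.2)
  # same distribution, long chains: PSRF -> 1
  same <- list(rnorm(5e4), rnorm(5e4))
  expect_lt(abs(psrf(same) - 1), 0.01)
  expect_error(psrf(list(rep(1, 10), rep(1, 10))), "degenerate")
  expect_error(psrf(list(rnorm(5), rnorm(6))), "equal length")
})

test_that("MPSRF matches its oracle, bounds the univariate PSRFs and
           reduces to PSRF in 1-D", {
  set.seed(43)
  for (i in 1:20) {
    m <- sample(2:4, 1); n <- sample(60:150, 1); p <- sample(1:4, 1)
    chains <- lapply(seq_len(m), function(j)
      matrix(rnorm(n * p, mean = j * runif(1, 0, 1)), n, p))
    expect_equal(mpsrf(chains), mpsrf_oracle(chains), tolerance = 1e-8)
    max_uni <- max(vapply(seq_len(p), function(k)
      psrf(lapply(chains, function(x) x[, k])), numeric(1)))
    expect_gte(mpsrf(chains) + 1e-12, max_uni)
  }
  x <- matrix(rnorm(100), 100, 1); y <- matrix(rnorm(100), 100, 1)
  expect_equal(mpsrf(list(x, y)), psrf(list(x[, 1], y[, 1])),
               tolerance = 1e-10)
  # identical chains: B vanishes
  expect_equal(mpsrf(list(x, x)), sqrt(99 / 100), tolerance = 1e-12)
  # perfectly collinear coordinates give a singular W
  z <- cbind(x, x)
  expect_error(mpsrf(list(z, z + 1)), "degenerate covariance")
})

test_that("the M-chain combining gate concatenates only same-basin chains", {
  efn <- function(th) sum(th^2) / 2
  st <- pt_settings(n_chains = 2, n_swaps = 220, n_mcmc = 5, burn_in = 20,
                    scale0 = 1)
  init <- rep(list(list(theta = c(0, 0), E = 0)), 2)
  runs <- lapply(1:3, function(s) run_pt(efn, init, st, seed = s))
  res <- combine_chains(runs)
  expect_true(res$passed)
  expect_lt(res$psrf_energy, 1.2)
  expect_equal(nrow(res$samples), 3 * 200)   # M x (N/M) = N
  expect_length(res$energy, 3 * 200)
  # an energy trace offset by a large constant fails the gate
  shifted <- runs[[3]]
  shifted$energy <- shifted$energy + 50
  res2 <- combine_chains(list(runs[[1]], runs[[2]], shifted))
  expect_false(res2$passed)
  expect_gt(res2$psrf_energy, 1.2)
  expect_null(res2$samples)
  # M = 1 passes through with a warning
  expect_warning(res3 <- combine_chains(runs[1]), "single store")
  expect_true(res3$passed)
  expect_true(is.na(res3$psrf_energy))
  # unequal lengths are a specification error
  st2 <- pt_settings(n_chains = 2, n_swaps = 120, n_mcmc = 5, burn_in = 20)
  short <- run_pt(efn, init, st2, seed = 9)
  expect_error(combine_chains(list(runs[[1]], short)), "equal length")
})

test_that("acceptance reports expose step and swap rates and flag
           undefined rates", {
  efn <- function(th) sum(th^2) / 2
  init <- rep(list(list(theta = c(0, 0), E = 0)), 3)
  st <- pt_settings(n_chains = 3, n_swaps = 60, n_mcmc = 5, burn_in = 20)
  run <- run_pt(efn, init, st, seed = 2)
  rep <- acceptance_report(run)
  expect_equal(nrow(rep$steps), 3)
  expect_equal(rep$steps$attempted, rep(40 * 5, 3))
  expect_true(all(rep$steps$rate >= 0 & rep$steps$rate <= 1))
  expect_equal(nrow(rep$swaps), 2)
  # an always-downhill energy accepts every move
  free <- local({n <- 0; function(th) {n <<- n - 1; n}})
  r2 <- run_pt(free, init[1],
               pt_settings(n_chains = 1, n_swaps = 30, n_mcmc = 5,
                           burn_in = 5), seed = 3)
  expect_equal(acceptance_report(r2)$steps$rate, 1)
  # single chain: no swap attempts, rates flagged undefined (empty)
  expect_equal(nrow(acceptance_report(r2)$swaps), 0)
})
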