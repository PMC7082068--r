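test_that("Gaussian proposal has the right moments and is symmetric", {
  set.seed(1)
  th <- c(-3, 2)
  d <- replicate(1e5, propose(th, 0.4)) - th
  expect_lt(max(abs(rowMeans(d))), 0.4 * 4 / sqrt(1e5))  # mean ~ 0
  expect_equal(unname(apply(d, 1, sd)), c(0.4, 0.4), tolerance = 0.02)
  # scale -> 0 limit leaves theta unchanged
  expect_equal(propose(th, 1e-300), th)
  expect_error(propose(th, 0), "> 0")
  # fixed seed reproduces the proposal sequence exactly
  set.seed(9); a <- replicate(5, propose(th, 1))
  set.seed(9); b <- replicate(5, propose(th, 1))
  expect_identical(a, b)
})

test_that("MH acceptance matches min(1, exp(-beta dE)) empirically", {
  # dE <= 0 is always accepted
  set.seed(2)
  s <- mh_step(c(0, 0), 10, function(th) 1, beta = 1)
  expect_true(s$accepted)
  # beta = 1, dE = ln 2: acceptance probability 1/2
  up <- function(E0) function(th) E0 + log(2)
  set.seed(3)
  acc <- mean(replicate(1e5, mh_step(0, 5, up(5), beta = 1)$accepted))
  expect_gte(acc, 0.49); expect_lte(acc, 0.51)
  # beta = 0.5, dE = 2 ln 2: same acceptance probability 1/2
  up2 <- function(th) 5 + 2 * log(2)
  set.seed(4)
  acc2 <- mean(replicate(1e5, mh_step(0, 5, up2, beta = 0.5)$accepted))
  expect_gte(acc2, 0.49); expect_lte(acc2, 0.51)
  # NaN energies reject
  set.seed(5)
  s <- mh_step(0, 5, function(th) NaN, beta = 1)
  expect_false(s$accepted)
  expect_equal(s$E, 5)
})

test_that("swap acceptance matches min(1, exp(dbeta dE)) empirically", {
  th <- rbind(c(0, 0), c(1, 1))
  # dbeta * dE >= 0 always swaps
  set.seed(6)
  sw <- attempt_swaps(th, c(5, 1), betas = c(1, 0.5))
  expect_true(sw$accepted)
  expect_equal(sw$E, c(1, 5))
  # dbeta = -0.5, dE = 2 -> probability exp(-1)
  set.seed(7)
  acc <- mean(replicate(1e5,
    attempt_swaps(th, c(0, 2), betas = c(1, 0.5))$accepted))
  expect_equal(acc, exp(-1), tolerance = 0.01)
  # identical states: swap is a no-op whatever the coin says
  set.seed(8)
  sw <- attempt_swaps(rbind(c(1, 2), c(1, 2)), c(3, 3), c(1, 0.5))
  expect_equal(sw$theta, rbind(c(1, 2), c(1, 2)))
})

test_that("burn-in adaptation moves scales toward 0.234 and then freezes", {
  s1 <- adapt_burn_in(0.5, rates = 0.5, swap_index = 1, burn_in = 10)
  expect_gt(s1, 0.5)                       # too many acceptances -> grow
  s2 <- adapt_burn_in(0.5, rates = 0.05, swap_index = 1, burn_in = 10)
  expect_lt(s2, 0.5)                       # too few -> shrink
  expect_error(adapt_burn_in(0.5, 0.3, swap_index = 11, burn_in = 10),
               "contract violation")
  # inside a run, scales are constant after burn-in
  efn <- function(th) sum(th^2) / 2
  init <- list(list(theta = c(0, 0), E = 0), list(theta = c(1, 1), E = 1))
  st <- pt_settings(n_chains = 2, n_swaps = 40, n_mcmc = 5, burn_in = 20)
  run <- run_pt(efn, init, st, seed = 1)
  st2 <- pt_settings(n_chains = 2, n_swaps = 20, n_mcmc = 5, burn_in = 20 - 1)
  expect_true(all(run$scales > 0))
})

test_that("prior-threshold initialization respects the threshold and
           reports failure on infeasible priors", {
  sp <- parameter_space(c("a", "b"), lower = -2, upper = 2)
  efn <- function(th) sum(th^2)
  set.seed(11)
  ch <- init_chains(sp, efn, 3, threshold = 0.5)
  expect_length(ch, 3)
  for (c in ch) expect_lt(c$E, 0.5)
  # threshold = +Inf accepts the first in-bounds draw
  set.seed(12)
  ch1 <- init_chains(sp, efn, 1, threshold = Inf)
  expect_true(is.finite(ch1[[1]]$E))
  # empty feasible set -> initialization failure carrying the best energy
  expect_error(
    init_chains(sp, function(th) Inf, 1, max_attempts = 20),
    "initialization failure")
  # warm start round-trips the stored energy
  ws <- matrix(c(0.5, -0.5), 1)
  ch2 <- init_chains(sp, efn, 2, mode = "warm-start", warm_start = ws)
  expect_equal(ch2[[1]]$E, efn(c(0.5, -0.5)), tolerance = 1e-6)
})

test_that("PT samples a 2-D Gaussian with correct mean and spread", {
  efn <- function(th) sum(th^2) / 2       # standard bivariate normal
  sp <- parameter_space(c("x", "y"), lower = -50, upper = 50)
  set.seed(21)
  init <- init_chains(sp, efn, 4, threshold = 5)
  st <- pt_settings(n_chains = 4, n_swaps = 11000, n_mcmc = 10,
                    burn_in = 1000, scale0 = 1)
  run <- run_pt(efn, init, st, seed = 33)
  sm <- pt_samples(run)
  expect_equal(nrow(sm), 10000)           # one sample per sampling swap
  # autocorrelated chain: allow ~3 standard errors with a generous ESS guess
  expect_lt(max(abs(colMeans(sm))), 0.1)
  expect_equal(unname(apply(sm, 2, sd)), c(1, 1), tolerance = 0.1)
})

test_that("runs are bit-reproducible and a single chain is plain MH", {
  efn <- function(th) sum(th^2) / 2
  init <- list(list(theta = c(0, 0), E = 0))
  st <- pt_settings(n_chains = 1, n_swaps = 50, n_mcmc = 5, burn_in = 10)
  r1 <- run_pt(efn, init, st, seed = 5)
  r2 <- run_pt(efn, init, st, seed = 5)
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$energy, r2$energy)
  expect_equal(r1$accept$swap_attempted, integer(0))
  init4 <- rep(list(list(theta = c(0, 0), E = 0)), 4)
  st4 <- pt_settings(n_chains = 4, n_swaps = 50, n_mcmc = 5, burn_in = 10)
  r3 <- run_pt(efn, init4, st4, seed = 5)
  r4 <- run_pt(efn, init4, st4, seed = 5)
  expect_identical(r3$theta, r4$theta)
  # rejection bookkeeping: sample count equals N regardless of acceptance
  hard <- function(th) if (any(abs(th) > 1e-4)) Inf else 0
  r5 <- run_pt(hard, init, st, seed = 6)
  expect_equal(nrow(pt_samples(r5)), 40)
})

test_that("tempering escapes a deep double well that traps plain MH", {
  # two wells at -3 and +9, 12 units apart, barrier height ~26
  efn <- function(th) 0.02 * (th[1] + 3)^2 * (th[1] - 9)^2
  init <- list(theta = -3, E = efn(-3))
  st_mh <- pt_settings(n_chains = 1, n_swaps = 400, n_mcmc = 10,
                       burn_in = 50, scale0 = 0.5)
  mh <- run_pt(efn, list(init), st_mh, seed = 13)
  st_pt <- pt_settings(n_chains = 4, beta_min = 0.02, n_swaps = 400,
                       n_mcmc = 10, burn_in = 50, scale0 = 0.5)
  pt <- run_pt(efn, rep(list(init), 4), st_pt, seed = 13)
  expect_lt(max(pt_samples(mh)), 3)        # MH never crosses the barrier
  expect_gt(max(pt_samples(pt)), 8)        # PT visits the second well
  expect_lt(min(pt_samples(pt)), -2)
})

test_that("the beta = 1 chain reproduces an analytic 1-D posterior
           (Gaussian likelihood x Laplace prior)", {
  y <- 0.3; sigma <- 0.5; mu <- -1; b <- 0.5
  efn <- function(th) (th - y)^2 / (2 * sigma^2) + abs(th - mu) / b
  init <- rep(list(list(theta = 0, E = efn(0))), 4)
  st <- pt_settings(n_chains = 4, n_swaps = 21000, n_mcmc = 10,
                    burn_in = 1000, scale0 = 0.8)
  run <- run_pt(efn, init, st, seed = 77)
  sm <- as.vector(pt_samples(run))
  expect_length(sm, 20000)
  grid <- seq(-6, 6, by = 1e-3)
  w <- exp(-vapply(grid, efn, numeric(1)))
  cdf <- cumsum(w) / sum(w)
  ks <- max(abs(ecdf(sm)(grid) - cdf))
  expect_lt(ks, 0.02)
})
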