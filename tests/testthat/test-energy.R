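make_k3_model <- function(prior = "laplace", mu = -10, b = 1,
                          constraints = NULL, soft = NULL) {
  net <- complete_unimolecular_network(3)
  truth <- c(k_AB = 0.1, k_BC = 1)
  tt <- k3_observation_times()
  tr <- simulate_network(net, ptlasso:::full_params(net, truth), tt)
  obs <- data.frame(species = "B", time = tt, mean = tr$values[, "B"],
                    sd = 0.3 * tr$values[, "B"])
  sp <- parameter_space(network_params(net), prior = prior, mu = mu, b = b)
  energy_model(net, obs, sp, constraints = constraints, soft = soft)
}

test_that("log likelihood reproduces the Gaussian residual formula", {
  tr <- structure(list(times = c(1, 2),
                       values = cbind(A = c(2, 3))),
                  class = "trajectory")
  perfect <- data.frame(species = "A", time = c(1, 2), mean = c(2, 3),
                        sd = c(1, 1))
  expect_equal(log_likelihood(tr, perfect), 0)
  # one observation with residual exactly sigma -> -0.5
  one <- data.frame(species = "A", time = 1, mean = 1, sd = 1)
  expect_equal(log_likelihood(tr, one), -0.5)
  # residuals sigma and 2*sigma -> -(1 + 4)/2
  two <- data.frame(species = "A", time = c(1, 2), mean = c(1, 1),
                    sd = c(1, 1))
  expect_equal(log_likelihood(tr, two), -2.5)
  # missing record is a specification error
  expect_error(
    log_likelihood(tr, data.frame(species = "A", time = 9, mean = 0, sd = 1)),
    "not on the trajectory")
  # non-finite simulation values give -Inf
  bad <- structure(list(times = 1, values = cbind(A = NaN)),
                   class = "trajectory")
  expect_identical(log_likelihood(bad, one), -Inf)
})

test_that("Laplace log prior is -|theta - mu| / b with the constant dropped", {
  expect_equal(laplace_log_prior(-10, -10, 1), 0)
  expect_equal(laplace_log_prior(-1, -10, 1), -9)
  expect_equal(laplace_log_prior(-1, -10, 0.5), -18)  # halving b doubles it
  expect_error(laplace_log_prior(0, 0, 0), "invalid hyperparameter")
  # the dropped constant is exactly the Laplace normalization: the density
  # exp(-|x - mu|/b) / (2b) integrates to 1
  grid <- seq(-60, 40, by = 1e-3)
  dens <- exp(laplace_log_prior(grid, -10, 1)) / (2 * 1)
  expect_equal(sum(dens) * 1e-3, 1, tolerance = 1e-4)
})

test_that("posterior energy decomposes into likelihood plus prior penalty", {
  em <- make_k3_model()
  set.seed(7)
  for (i in 1:10) {
    th <- runif(6, -12, 3)
    manual <- -em$loglik(th) + sum(abs(th - (-10)) / 1)
    expect_equal(em$energy(th), manual, tolerance = 1e-12)
  }
  # uniform priors: energy is exactly -logL inside the box
  emu <- make_k3_model(prior = "uniform")
  th <- runif(6, -12, 3)
  expect_equal(emu$energy(th), -emu$loglik(th), tolerance = 1e-12)
  # at the prior mode with a perfect fit the penalty vanishes
  th0 <- log10(c(0.1, 1e-10, 1e-10, 1, 1e-10, 1e-10))
  names(th0) <- network_params(complete_unimolecular_network(3))
  th0[] <- -10
  expect_equal(em$energy(th0), -em$loglik(th0), tolerance = 1e-12)
})

test_that("leaving the sampling box gives infinite energy", {
  em <- make_k3_model()
  th <- rep(-5, 6)
  expect_true(is.finite(em$energy(th)))
  expect_identical(em$energy(replace(th, 3, 3.01)), Inf)
  expect_identical(em$energy(replace(th, 1, -12.5)), Inf)
})

test_that("hard constraints are strict and evaluated in log space", {
  cs <- hard_constraints("k_AB > k_BC")
  expect_true(check_hard_constraints(c(k_AB = 1, k_BC = 0), cs)$pass)
  chk <- check_hard_constraints(c(k_AB = 0, k_BC = 0), cs)
  expect_false(chk$pass)                      # strict inequality
  expect_identical(chk$violated, "k_AB > k_BC")
  expect_true(check_hard_constraints(c(k_AB = 0), NULL)$pass)  # empty set
  expect_error(check_hard_constraints(c(a = 1), cs), "unknown parameter")
  em <- make_k3_model(constraints = cs)
  th <- rep(-5, 6)
  expect_identical(em$energy(th), Inf)        # k_AB = k_BC violates
  expect_true(is.finite(em$energy(replace(th, 1, -4))))
})

test_that("soft constraints add a finite quadratic penalty", {
  sc <- soft_constraint(
    feature = function(trajs) trajs[[1]]$values[nrow(trajs[[1]]$values), "B"],
    target = 0, weight = 2)
  em0 <- make_k3_model()
  em1 <- make_k3_model(soft = list(sc))
  th <- rep(-5, 6)
  pred <- em1$predict_obs(10^th, keep_traj = TRUE)
  feat <- pred$trajs[[1]]$values[8, "B"]
  expect_equal(em1$energy(th), em0$energy(th) + 2 * feat^2,
               tolerance = 1e-10)
})

test_that("grouped energy composes theta' = k' + lambda' with an open box", {
  net <- modular_toy_network()
  truth <- modular_toy_truth()
  sch <- modular_toy_protocol("pulse")
  tt <- modular_toy_observation_times("pulse")
  tr <- simulate_network(net, truth, tt, inputs = sch)
  obs <- data.frame(species = "R", time = tt, mean = tr$values[, "R"],
                    sd = 0.1 * tr$values[, "R"])
  gs <- grouped_spec(mu = -25, b = 2, lb = -5, ub = 10)
  em <- energy_model(net, obs, experiments = list("1" = sch), grouped = gs)
  mods <- unique(unname(network_modules(net)))
  lam <- setNames(rep(-25, 3), paste0("lambda_", mods))
  kp <- setNames(rep(0, 7), network_params(net))
  # all k' inside (lb, ub) and lambda' = mu: zero penalty, pure misfit
  E0 <- grouped_energy(lam, kp, em)
  expect_true(is.finite(E0))
  expect_equal(E0, -em$loglik(c(lam, kp)), tolerance = 1e-10)
  # shifting one lambda adds |lambda - mu| / b
  lam2 <- replace(lam, 1, -21)
  expect_equal(grouped_energy(lam2, kp, em),
               -em$loglik(c(lam2, kp)) + 4 / 2, tolerance = 1e-10)
  # the reaction-specific box is open: the boundary itself is infinite
  expect_identical(grouped_energy(lam, replace(kp, 1, -5), em), Inf)
  expect_identical(grouped_energy(lam, replace(kp, 2, 10), em), Inf)
  # with the defaults the largest shrunk rate ~ 10^(UB + mu) cannot move
  # the dynamics: energy equals the dead-network misfit exactly
  kp_hi <- setNames(rep(10 - 1e-9, 7), network_params(net))
  dead <- sum(obs$mean^2 / (2 * pmax(obs$sd, 0.01 * max(obs$mean))^2))
  expect_equal(grouped_energy(lam, kp_hi, em), dead, tolerance = 1e-6)
  # grouped model requires module labels
  expect_error(
    energy_model(complete_unimolecular_network(3), obs, grouped = gs),
    "module labels")
})

test_that("a single wide module with k' = 0 reduces to the plain Lasso
           energy on lambda", {
  net <- reaction_network(
    c("A", "B"),
    list(reaction("A", "B", param = "k_AB", module = "only")),
    c(A = 100))
  tt <- c(1, 2, 4)
  tr <- simulate_network(net, c(k_AB = 0.5), tt)
  obs <- data.frame(species = "B", time = tt, mean = tr$values[, "B"],
                    sd = rep(1, 3))
  gs <- grouped_spec(mu = -10, b = 1, lb = -30, ub = 30,
                     lambda_lower = -12, lambda_upper = 3)
  emg <- energy_model(net, obs, experiments = NULL, grouped = gs)
  sp <- parameter_space("k_AB", prior = "laplace", mu = -10, b = 1)
  eml <- energy_model(net, obs, sp)
  for (th in c(-2, -0.301, 0.5)) {
    expect_equal(grouped_energy(th, 0, emg), eml$energy(th),
                 tolerance = 1e-10)
  }
})

test_that("simulation failure maps to infinite energy inside the sampler", {
  net <- reaction_network(
    c("A", "B"),
    list(reaction(c(A = 2L), c(A = 3L), param = "k_auto"),
         reaction("A", "B", param = "k_dec")),
    c(A = 10))
  obs <- data.frame(species = "B", time = c(50, 100), mean = c(5, 8),
                    sd = c(1, 1))
  em <- energy_model(net, obs,
                     parameter_space(c("k_auto", "k_dec"),
                                     lower = -12, upper = 8))
  expect_identical(em$energy(c(6, -12)), Inf)   # blows up in finite time
  expect_true(is.finite(em$energy(c(-6, -2))))
})
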