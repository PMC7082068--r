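test_that("reaction and network constructors enforce their invariants", {
  r <- reaction("A", "B", param = "k1")
  expect_s3_class(r, "reaction")
  expect_identical(r$reactants, c(A = 1L))
  expect_error(reaction(c(A = 0.5), "B", param = "k"),
               "positive integers")
  expect_error(reaction(c(A = -1L), "B", param = "k"),
               "positive integers")
  expect_error(
    reaction_network("A", list(reaction("A", "B", param = "k"))),
    "unknown species")
  expect_error(
    reaction_network(c("A", "B"),
                     list(reaction("A", "B", param = "k"),
                          reaction("B", "A", param = "k")),
                     c(A = 1)),
    "unique")
  expect_error(
    reaction_network(c("A", "B"),
                     list(reaction("A", "B", param = "k")),
                     c(A = -1)),
    ">= 0")
  # module labels must cover all reactions or none
  expect_error(
    reaction_network(c("A", "B"),
                     list(reaction("A", "B", param = "k1", module = "m"),
                          reaction("B", "A", param = "k2")),
                     c(A = 1)),
    "module")
})

test_that("complete unimolecular networks have n(n-1) conversions", {
  k3 <- complete_unimolecular_network(3)
  expect_length(k3$reactions, 6)
  expect_setequal(network_params(k3),
                  c("k_AB", "k_AC", "k_BA", "k_BC", "k_CA", "k_CB"))
  expect_equal(unname(k3$initial_state), c(100, 0, 0))
  expect_length(complete_unimolecular_network(5)$reactions, 20)
  expect_error(complete_unimolecular_network(1), "invalid network")
  # n = 2: two reactions, total abundance conserved under simulation
  k2 <- complete_unimolecular_network(2)
  expect_length(k2$reactions, 2)
  tr <- simulate_network(k2, c(k_AB = 0.3, k_BA = 0.7), seq(0, 10, 0.5))
  expect_equal(rowSums(tr$values), rep(100, length(tr$times)),
               tolerance = 1e-8)
})

test_that("dose-response prior network realizes both Tyson motifs", {
  net <- dose_response_network()
  expect_length(net$reactions, 6)
  k <- setNames(rep(1e-12, 6), network_params(net))
  # linear submodel: steady state R* = (k_srs / k_r0) * S, linear in S
  kl <- replace(k, c("k_srs", "k_r0"), c(10, 0.01))
  Rstar <- vapply(1:3, function(S) {
    sch <- data.frame(name = "S", value = S, start = 0, end = 2000)
    trajectory_value(simulate_network(net, kl, c(0, 2000), inputs = sch),
                     "R", 2000)
  }, numeric(1))
  expect_equal(Rstar, 1000 * (1:3), tolerance = 1e-4)
  # adaptive submodel: steady state independent of S (perfect adaptation)
  ka <- replace(k, c("k_srs", "k_xrx", "k_sxs", "k_x0"), c(10, 10, 1, 1))
  Rad <- vapply(1:2, function(S) {
    sch <- data.frame(name = "S", value = S, start = 0, end = 60)
    trajectory_value(simulate_network(net, ka, c(0, 50, 60), inputs = sch),
                     "R", 60)
  }, numeric(1))
  expect_equal(Rad[1], 10 * 1 / (10 * 1), tolerance = 1e-4)
  expect_lt(abs(Rad[2] - Rad[1]) / Rad[1], 1e-3)
  # S = 0: R and X stay at their initial values when basal rates are zero
  tr0 <- simulate_network(net, ka, c(0, 5, 10), inputs = NULL)
  expect_equal(max(abs(tr0$values[, c("R", "X")])), 0)
})

test_that("modular toy network partitions its reactions into three modules", {
  net <- modular_toy_network()
  expect_lte(length(net$species), 8)
  mods <- network_modules(net)
  expect_false(is.null(mods))
  expect_setequal(unique(unname(mods)), c("activation", "output", "feedback"))
  # partition: every reaction carries exactly one module label
  expect_length(mods, length(net$reactions))
  expect_false(anyNA(mods))
})

test_that("feedback module is dispensable under a pulse, required under
           continuous stimulation", {
  net <- modular_toy_network()
  truth <- modular_toy_truth()
  floor_fb <- replace(truth, c("k_fprod", "k_fb", "k_fdec"), 1e-12)
  dev_sigma <- function(protocol) {
    sch <- modular_toy_protocol(protocol)
    tt <- modular_toy_observation_times(protocol)
    full <- simulate_network(net, truth, tt, inputs = sch)$values[, "R"]
    red <- simulate_network(net, floor_fb, tt, inputs = sch)$values[, "R"]
    sigma <- pmax(0.1 * full, 0.01 * max(full))  # likelihood sigma scale
    max(abs(full - red) / sigma)
  }
  expect_lt(dev_sigma("pulse"), 1)        # within likelihood tolerance
  expect_gt(dev_sigma("continuous"), 5)   # fit degraded well beyond noise
})

test_that("network YAML files round-trip", {
  for (fixture in c("network-k3.yaml", "network-dose-response.yaml",
                    "network-modular-toy-synthetic.yaml")) {
    path <- system.file("extdata", fixture, package = "ptlasso")
    expect_true(file.exists(path))
    net <- read_network(path)
    tmp <- withr::local_tempfile(fileext = ".yaml")
    write_network(net, tmp)
    net2 <- read_network(tmp)
    expect_equal(net2, net)
  }
})
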