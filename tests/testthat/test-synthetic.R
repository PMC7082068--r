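test_that("trajectory-noise generator reduces to the truth at zero noise", {
  net <- complete_unimolecular_network(3)
  tt <- k3_observation_times()
  obs <- generate_observed(net, true_params("k3"), tt, species = "B",
                           noise_frac = 0, n_rep = 5, seed = 1)
  tr <- simulate_network(net, ptlasso:::full_params(net, true_params("k3")),
                         tt)
  expect_equal(obs$mean, unname(tr$values[, "B"]), tolerance = 1e-9)
  expect_equal(obs$sd, rep(0, 8))
  expect_error(generate_observed(net, true_params("k3"), tt, n_rep = 1),
               "n_rep")
})

test_that("K3 fixture has the study dimensions and seeds reproducibly", {
  obs <- generate_dataset("k3", seed = 7)
  expect_equal(nrow(obs), 8)
  expect_true(all(obs$species == "B"))
  prov <- attr(obs, "provenance")
  expect_equal(prov$n_rep, 10)
  # replicate means stay within the CLT envelope of the truth:
  # |mean - truth| < 4 * (0.3 truth) / sqrt(10) at each point
  net <- attr(obs, "network")
  tr <- simulate_network(net, ptlasso:::full_params(net, true_params("k3")),
                         obs$time)
  truth <- unname(tr$values[, "B"])
  for (s in 1:8) {
    o <- generate_dataset("k3", seed = s)
    expect_true(all(abs(o$mean - truth) < 4 * 0.3 * truth / sqrt(10)))
  }
  # bit-reproducibility
  expect_identical(as.data.frame(generate_dataset("k3", seed = 7)),
                   as.data.frame(obs))
  expect_false(identical(as.data.frame(generate_dataset("k3", seed = 8)),
                         as.data.frame(obs)))
})

test_that("variance-reading flag changes the noise scale as documented", {
  net <- complete_unimolecular_network(3)
  tt <- k3_observation_times()
  o_sd <- generate_observed(net, true_params("k3"), tt, species = "B",
                            noise_frac = 0.3, n_rep = 200, seed = 2,
                            noise_on = "sd")
  o_var <- generate_observed(net, true_params("k3"), tt, species = "B",
                             noise_frac = 0.3, n_rep = 200, seed = 2,
                             noise_on = "variance")
  tr <- simulate_network(net, ptlasso:::full_params(net, true_params("k3")),
                         tt)
  truth <- unname(tr$values[, "B"])
  # sd reading: replicate sd ~ 0.3 * truth; variance reading: sqrt(0.3 truth)
  expect_equal(o_sd$sd, 0.3 * truth, tolerance = 0.25)
  expect_equal(o_var$sd, sqrt(0.3 * truth), tolerance = 0.25)
})

test_that("parameter-noise generator perturbs in log space", {
  net <- complete_unimolecular_network(3)
  tt <- k3_observation_times()
  # zero log-noise reproduces the truth trajectory with zero sd
  o0 <- generate_param_noise_observed(net, c(k_AB = -1, k_BC = 0), tt,
                                      species = "B", sd_log = 0, n_rep = 3,
                                      seed = 1)
  tr <- simulate_network(net, ptlasso:::full_params(net, true_params("k3")),
                         tt)
  expect_equal(o0$mean, unname(tr$values[, "B"]), tolerance = 1e-8)
  expect_equal(o0$sd, rep(0, 8), tolerance = 1e-12)
  # S3-regime fixture is reproducible and carries its provenance
  o <- generate_dataset("k3-paramnoise", seed = 4)
  expect_identical(as.data.frame(generate_dataset("k3-paramnoise", seed = 4)),
                   as.data.frame(o))
  expect_equal(attr(o, "provenance")$generator,
               "generate_param_noise_observed")
})

test_that("dose-response protocols produce the documented experiments", {
  lin <- dose_response_protocol("linear")
  expect_length(lin, 4)
  expect_equal(vapply(lin, function(e) e$inputs$value, numeric(1)), 1:4)
  expect_true(all(vapply(lin, function(e) 0 %in% e$obs_times, logical(1))))
  # 4 doses x 4 time points = 16 observation records
  obs <- generate_dataset("dose-linear", seed = 1)
  expect_equal(nrow(obs), 16)
  expect_length(attr(obs, "experiments"), 4)
  # adapting protocol: piecewise-constant S with one internal step
  ad <- dose_response_protocol("adapting")
  expect_length(ad, 1)
  expect_equal(nrow(ad[[1]]$inputs), 2)
  expect_equal(ad[[1]]$inputs$value, c(1, 2))
  expect_equal(ad[[1]]$inputs$end[1], ad[[1]]$inputs$start[2])
  # zero doses: empty experiment list
  expect_length(dose_response_protocol("linear", doses = numeric()), 0)
})

test_that("observed datasets round-trip through TSV with provenance", {
  plain <- function(x) {
    x <- as.data.frame(x)
    data.frame(x[c("experiment", "species", "time", "mean", "sd")])
  }
  obs <- generate_dataset("k3", seed = 5)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_observed(obs, tmp)
  expect_true(file.exists(paste0(tmp, ".json")))
  back <- read_observed(tmp)
  expect_equal(plain(back), plain(obs), tolerance = 1e-12)
  # provenance closure: the sidecar regenerates the dataset exactly
  regen <- regenerate_observed(attr(obs, "network"),
                               attr(back, "provenance"))
  expect_equal(plain(regen), plain(obs), tolerance = 1e-14)
})
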