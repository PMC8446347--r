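test_that("truncated-Gaussian weights are nonnegative with ~half zeros", {
  J <- make_excitatory_weights(200, sigma = 0.05, seed = 11)
  expect_true(all(J$weights >= 0))
  frac0 <- mean(J$weights == 0)
  se <- sqrt(0.25 / 200^2)
  expect_lt(abs(frac0 - 0.5), 3 * se)
  expect_true(all(J$cell_class == "excitatory"))
})

test_that("mean truncated weight matches sigma/sqrt(2*pi)", {
  ## E[max(g, 0)] for g ~ N(0, sigma^2); entry sd ~ 0.0292 -> 3 SE over 40000
  J <- make_excitatory_weights(200, sigma = 0.05, seed = 2)
  expect_lt(abs(mean(J$weights) - 0.05 / sqrt(2 * pi)),
            3 * 0.0292 / 200)
})

test_that("generation is seed-reproducible", {
  a <- make_excitatory_weights(50, seed = 7)
  b <- make_excitatory_weights(50, seed = 7)
  expect_identical(a$weights, b$weights)
  expect_identical(make_ei_weights(50, seed = 7)$weights,
                   make_ei_weights(50, seed = 7)$weights)
})

test_that("E/I matrix scales inhibitory-sender columns by g_i exactly", {
  Je <- make_excitatory_weights(40, sigma = 0.05, seed = 3)
  Jb <- make_ei_weights(40, sigma = 0.05, g_i = -1.5, seed = 3)
  expect_identical(Jb$cell_class, rep(c("excitatory", "inhibitory"),
                                      each = 20))
  expect_equal(Jb$weights[, 1:20], Je$weights[, 1:20])
  expect_equal(Jb$weights[, 21:40], -1.5 * Je$weights[, 21:40])
  expect_true(all(Jb$weights[, 21:40] <= 0))
})

test_that("the balanced matrix is dominated by inhibition on average", {
  J <- make_ei_weights(200, sigma = 0.05, g_i = -1.5, seed = 5)
  expected <- 0.05 / sqrt(2 * pi) * (1 + (-1.5)) / 2
  expect_lt(mean(J$weights), 0)
  expect_lt(abs(mean(J$weights) - expected), 3 * 0.05 / 200)
})

test_that("adaptation strength is the mean summed input weight", {
  J <- zero_connectivity(3)
  expect_identical(adaptation_strength(J), 0)
  J$weights[] <- 1
  expect_equal(adaptation_strength(J), 3)
  J200 <- make_excitatory_weights(200, sigma = 0.05, seed = 4)
  ## expectation N * sigma / sqrt(2*pi) ~ 3.989; MC sd of the mean row sum
  expect_lt(abs(adaptation_strength(J200) - 200 * 0.05 / sqrt(2 * pi)),
            3 * 0.0292 * 200 / sqrt(200^2))
})

test_that("scale_inhibition is identity at 1, removes inhibition at 0", {
  J <- make_ei_weights(40, seed = 9)
  expect_identical(scale_inhibition(J, 1)$weights, J$weights)
  J0 <- scale_inhibition(J, 0)
  expect_true(all(J0$weights[, 21:40] == 0))
  expect_identical(J0$weights[, 1:20], J$weights[, 1:20])
  expect_error(scale_inhibition(J, 1.5), "\\[0, 1\\]")
  expect_error(scale_inhibition(make_excitatory_weights(10, seed = 1), 0.5),
               "inhibitory")
})

test_that("degenerate generation arguments are rejected", {
  expect_error(make_excitatory_weights(1), ">= 2")
  expect_error(make_excitatory_weights(10, sigma = 0), "sigma")
  expect_error(make_ei_weights(11), "even")
  expect_error(make_ei_weights(10, g_i = 0.5), "negative")
})

test_that("reducing inhibition never lowers simulated peak rates", {
  ## cooperative dynamics: attenuating inhibitory columns is monotone
  cfg <- experiment_config("balanced", seed = 3)
  J <- make_ei_weights(cfg$N, cfg$sigma, cfg$g_i, cfg$seed)
  params <- network_params(cfg$N, g_w = 0)
  drive <- pulse_protocol(cfg$baseline, cfg$amplitudes)
  peaks <- lapply(c(1, 0.5, 0), function(fac) {
    sim <- simulate_network(scale_inhibition(J, fac), params,
                            drive = drive)
    apply(peak_rates(sim)$peaks, 1, max)
  })
  expect_true(all(peaks[[2]] >= peaks[[1]] - 1e-8))
  expect_true(all(peaks[[3]] >= peaks[[2]] - 1e-8))
})

test_that("connectivity round-trips through CSV + JSON sidecar", {
  J <- make_ei_weights(20, sigma = 0.05, g_i = -1.5, seed = 13)
  path <- file.path(tempdir(), "J.csv")
  write_connectivity(J, path)
  J2 <- read_connectivity(path)
  expect_equal(J2$weights, J$weights, tolerance = 1e-12)
  expect_identical(J2$cell_class, J$cell_class)
  expect_equal(J2$g_i, J$g_i)
})
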