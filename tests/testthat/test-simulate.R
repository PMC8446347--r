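test_that("a decoupled neuron follows the closed-form exponential decay", {
  J <- zero_connectivity(3)
  p <- network_params(N = 3, g_w = 0)
  d <- constant_drive(0, duration = 250)  # 5 * tau_m
  c0 <- 4
  sim <- simulate_network(J, p, drive = d, dt = 1, x0 = c0, w0 = 0)
  exact <- c0 * exp(-sim$times / 50)
  err1 <- max(abs(sim$x[, 1] - exact))
  expect_lt(err1, 0.05 * c0)

  sim2 <- simulate_network(J, p, drive = d, dt = 0.5, x0 = c0, w0 = 0)
  err2 <- max(abs(sim2$x[, 1] - c0 * exp(-sim2$times / 50)))
  expect_lt(err2, err1)                     # halving dt shrinks the error...
  expect_gt(err1 / err2, 1.6)               # ...approximately linearly
  expect_lt(err1 / err2, 2.4)
})

test_that("a decoupled neuron converges to a constant drive level", {
  J <- zero_connectivity(2)
  p <- network_params(N = 2, g_w = 0)
  d <- constant_drive(3.7, duration = 1000)  # 20 * tau_m
  sim <- simulate_network(J, p, drive = d, x0 = 0, w0 = 0)
  expect_equal(unname(sim$x[nrow(sim$x), ]), c(3.7, 3.7), tolerance = 1e-4)
})

test_that("rates equal phi(x) at every sample and stay inside (0, ceiling)", {
  J <- make_excitatory_weights(60, seed = 21)
  p <- network_params(N = 60, g_w = adaptation_strength(J))
  sim <- simulate_network(J, p, drive = pulse_protocol(-20, c(30, 50),
                                                       width = 400,
                                                       gap = 400))
  expect_equal(sim$r, firing_rate(sim$x, sim$f))
  expect_true(all(sim$r > 0))
  expect_true(all(sim$r < rate_ceiling(sim$f)))
})

test_that("identical inputs give bit-identical trajectories", {
  run <- function() {
    J <- make_excitatory_weights(40, seed = 5)
    p <- network_params(N = 40, g_w = adaptation_strength(J))
    simulate_network(J, p, drive = pulse_protocol(-20, 30, width = 300,
                                                  gap = 300))
  }
  a <- run(); b <- run()
  expect_identical(a$r, b$r)
  expect_identical(a$w, b$w)
})

test_that("default initial condition is the silent holding state", {
  J <- make_excitatory_weights(200, seed = 6)
  p <- network_params(g_w = adaptation_strength(J))
  sim <- simulate_network(J, p, drive = constant_drive(-20, 2000))
  ## no onset burst: the supercritical network stays quiet under the hold
  expect_lt(max(sim$r), 0.05 * rate_ceiling(sim$f))
  expect_equal(unname(sim$x[1, ]), rep(-20, 200))
})

test_that("dimension and step-size preconditions are enforced", {
  J <- make_excitatory_weights(10, seed = 1)
  expect_error(simulate_network(J, network_params(N = 20),
                                drive = constant_drive(0, 100)),
               "10 x 10")
  expect_error(simulate_network(J, network_params(N = 10),
                                drive = constant_drive(0, 100), dt = 10),
               "dt")
  expect_error(simulate_network(J, network_params(N = 10),
                                drive = constant_drive(0, 100), x0 = Inf),
               "finite")
})

test_that("simulation serializes to long CSV plus JSON summary", {
  J <- make_excitatory_weights(5, seed = 2)
  sim <- simulate_network(J, network_params(N = 5, g_w = 0),
                          drive = constant_drive(-1, 50))
  df <- as.data.frame(sim)
  expect_named(df, c("time", "neuron_id", "x", "w", "r"))
  expect_equal(nrow(df), 5 * length(sim$times))
  path <- file.path(tempdir(), "sim.csv")
  write_sim(sim, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_length(meta$peak_rates, 5)
  expect_equal(meta$params$tau_m, 50)
})
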