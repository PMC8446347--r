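test_that("skewness of a symmetric triple is zero", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  expect_error(sample_skewness(rep(2, 10)), "constant")
  expect_error(sample_skewness(c(1, 2)), ">= 3")
})

test_that("skewness is translation- and positive-scale-invariant", {
  set.seed(8)
  for (i in 1:5) {
    v <- rgamma(200, shape = 2)
    s <- sample_skewness(v)
    expect_equal(sample_skewness(v + 13.7), s, tolerance = 1e-10)
    expect_equal(sample_skewness(3.2 * v), s, tolerance = 1e-10)
  }
})

test_that("skewness matches the independent type-2 implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  v <- rlnorm(500, 0, 0.7)
  expect_equal(sample_skewness(v), e1071::skewness(v, type = 2),
               tolerance = 1e-12)
})

test_that("lognormal samples show the closed-form skewness, logs show none", {
  set.seed(31)
  v <- rlnorm(1e5, 0, 0.5)
  expect_lt(abs(sample_skewness(v) - lognormal_skewness(0.5)), 0.1)
  expect_lt(abs(sample_skewness(log(v))), 0.05)
})

test_that("lognormal MLE recovers generating parameters", {
  set.seed(7)
  v <- rlnorm(2000, meanlog = 1, sdlog = 0.5)
  fit <- fit_lognormal(v)
  expect_lt(abs(fit$meanlog - 1), 0.05)
  expect_lt(abs(fit$sdlog - 0.5), 0.05)
})

test_that("lognormal MLE agrees with the independent fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(15)
  v <- rlnorm(800, 0.3, 0.8)
  fit <- fit_lognormal(v)
  ref <- fitdistrplus::fitdist(v, "lnorm")
  expect_equal(fit$meanlog, unname(ref$estimate["meanlog"]),
               tolerance = 1e-4)
  expect_equal(fit$sdlog, unname(ref$estimate["sdlog"]), tolerance = 1e-4)
})

test_that("degenerate lognormal fits behave as specified", {
  fit <- fit_lognormal(rep(4, 20))
  expect_equal(fit$meanlog, log(4))
  expect_equal(fit$sdlog, 0)
  expect_error(fit_lognormal(c(rep(1, 20), 0)), "> 0")
  expect_error(fit_lognormal(1:5), ">= 10")
})

test_that("refitting data generated from a fitted law reproduces skewness", {
  set.seed(22)
  orig <- rlnorm(1e4, 0.2, 0.4)
  fit <- fit_lognormal(orig)
  reps <- vapply(1:5, function(i)
    sample_skewness(rlnorm(1e4, fit$meanlog, fit$sdlog)), numeric(1))
  tol <- 3 * stats::sd(reps) + 1e-3
  expect_lt(abs(sample_skewness(orig) - mean(reps)), tol)
})

test_that("peak extraction returns the windowed maxima", {
  J <- zero_connectivity(4)
  sim <- simulate_network(J, network_params(N = 4, g_w = 0),
                          drive = constant_drive(2, 600))
  pd <- peak_rates(sim, windows = list(c(400, 600)))
  ## decoupled neurons settle at x = 2, so every peak is phi(2)
  expect_equal(unname(pd$peaks[, 1]), rep(firing_rate(2, sim$f), 4),
               tolerance = 1e-6)
  expect_error(peak_rates(sim, windows = list(c(500, 400))), "start < end")
  expect_error(peak_rates(sim, windows = list(c(500, 900))), "span")
  expect_error(peak_rates(sim, windows = list()), "no windows")
})

test_that("peak_stats summarizes each window", {
  b <- run_balanced(small_config("balanced", seed = 2))
  st <- peak_stats(b$peaks)
  expect_equal(nrow(st), 2)
  expect_named(st, c("window", "n", "mean_peak", "skew_linear", "skew_log",
                     "lognorm_mu", "lognorm_sigma", "mode_estimate",
                     "top_bin_frac"))
  expect_true(all(st$n == 100))
  expect_true(all(st$mode_estimate > 0 & st$mode_estimate < 90))
})

test_that("response curves demand a shared network and sort by amplitude", {
  J <- make_ei_weights(60, seed = 1)
  p <- network_params(N = 60, g_w = 0)
  sims <- lapply(c(40, 20), function(a)
    simulate_network(J, p, drive = pulse_protocol(-20, a, width = 300,
                                                  gap = 300)))
  rc <- response_curve(sims)
  expect_equal(rc$amplitude, c(20, 40))
  expect_true(all(diff(rc$mean_peak) > 0))
  J2 <- make_ei_weights(60, seed = 2)
  sims[[2]] <- simulate_network(J2, p,
                                drive = pulse_protocol(-20, 20, width = 300,
                                                       gap = 300))
  expect_error(response_curve(sims), "same network")
})
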