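test_that("noiseless degenerate amplitudes reproduce the peak dF/F exactly", {
  ds <- generate_calcium_dataset(n_animals = 2, n_cells = 5,
                                 amp_pars = c(meanlog = log(0.8), sdlog = 0),
                                 noise_sd = 0, seed = 1)
  for (p in peak_dff(ds))
    expect_equal(unname(p), rep(0.8, 5), tolerance = 1e-10)
})

test_that("dF/F handles the elementary cases", {
  tt <- seq(0, 10, by = 0.1)
  expect_true(all(delta_f_over_f(rep(5, length(tt)), tt, c(0, 2)) == 0))
  tr <- rep(3, length(tt)); tr[50] <- 6
  expect_equal(max(delta_f_over_f(tr, tt, c(0, 2))), 1)
  expect_error(delta_f_over_f(rep(0, length(tt)), tt, c(0, 2)),
               "nonpositive")
})

test_that("noiseless peak extraction inverts generation", {
  ds <- generate_calcium_dataset(n_animals = 1, n_cells = 40,
                                 noise_sd = 0, seed = 5)
  expect_equal(unname(peak_dff(ds)[[1]]), ds$animals[[1]]$amplitudes,
               tolerance = 1e-8)
})

test_that("a lognormal cohort is skewed linearly but not on the log scale", {
  ds <- generate_calcium_dataset(seed = 20)  # 10 animals x 50 cells
  res <- cohort_skewness_analysis(ds)
  expect_equal(nrow(res), 10)
  expect_true(all(res$skew_linear > 0))
  expect_lt(attr(res, "mean_abs_skew_log"), attr(res, "mean_skew_linear"))
})

test_that("normal amplitudes give symmetric peak distributions", {
  ds <- generate_calcium_dataset(n_animals = 10, n_cells = 200,
                                 amp_family = "normal",
                                 amp_pars = c(mean = 1, sd = 0.15),
                                 noise_sd = 0, seed = 9)
  res <- cohort_skewness_analysis(ds)
  ## skewness SE ~ sqrt(6/200) = 0.17 per animal; cohort mean SE ~ 0.055
  expect_lt(abs(mean(res$skew_linear)), 3 * sqrt(6 / 200) / sqrt(10))
})

test_that("normal amplitude models with negative mass are rejected", {
  expect_error(generate_calcium_dataset(amp_family = "normal",
                                        amp_pars = c(mean = 1, sd = 0.6)),
               "below zero")
})

test_that("lognormal parameters are recovered from a large animal", {
  ds <- generate_calcium_dataset(n_animals = 1, n_cells = 500,
                                 amp_pars = c(meanlog = -0.5, sdlog = 0.6),
                                 noise_sd = 0, seed = 33)
  res <- cohort_skewness_analysis(ds)
  expect_lt(abs(res$lognorm_mu + 0.5), 3 * 0.6 / sqrt(500))
  expect_lt(abs(res$lognorm_sigma - 0.6), 3 * 0.6 / sqrt(1000))
})

test_that("noise inflates the spread of peak estimates monotonically", {
  ## same seed -> identical amplitudes and noise shape across levels, so
  ## the spread of the estimation error scales with noise_sd
  err_spread <- vapply(c(0, 1, 3), function(ns) {
    ds <- generate_calcium_dataset(n_animals = 1, n_cells = 100,
                                   noise_sd = ns, seed = 77)
    stats::sd(peak_dff(ds)[[1]] - ds$animals[[1]]$amplitudes)
  }, numeric(1))
  expect_true(all(diff(err_spread) > 0))
  expect_equal(err_spread[1], 0, tolerance = 1e-8)
})

test_that("a dataset round-trips through per-animal CSV + JSON", {
  ds <- generate_calcium_dataset(n_animals = 3, n_cells = 12, seed = 2)
  dir <- file.path(tempdir(), "calcium_rt")
  write_calcium_dataset(ds, dir)
  ds2 <- read_calcium_dataset(dir)
  expect_equal(length(ds2$animals), 3)
  expect_equal(ds2$times, ds$times)
  expect_equal(ds2$animals[[2]]$F, ds$animals[[2]]$F, tolerance = 1e-10)
  expect_equal(ds2$animals[[3]]$amplitudes, ds$animals[[3]]$amplitudes)
  expect_equal(cohort_skewness_analysis(ds2)$skew_linear,
               cohort_skewness_analysis(ds)$skew_linear, tolerance = 1e-8)
})
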