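#' Experiment configuration
#'
#' A single resolved configuration object consumed by the experiment
#' runners. Defaults reproduce the study conditions: N = 200 neurons,
#' truncated-Gaussian weights of width sigma = 0.05, inhibitory factor
#' g_i = -1.5 for the balanced architecture, tau_m = 50 ms, tau_a = 300
#' ms, rate function r0 = 10 / rmax = 80, and a three-pulse drive
#' protocol of increasing amplitude on a negative holding baseline.
#'
#' @param experiment one of `"excitatory"`, `"balanced"`,
#'   `"response-curve"`, `"block-inhibition"`, `"branching"`, `"calcium"`.
#' @param N,sigma,g_i connectivity parameters.
#' @param r0,rmax rate-function parameters.
#' @param tau_m,tau_a,dt integration parameters (ms).
#' @param baseline,amplitudes,pulse_width,pulse_gap drive protocol.
#' @param inhibition_factor attenuation of inhibitory weights in \[0, 1\]
#'   (block-inhibition experiment), default 0 (full block).
#' @param branching_m,branching_trials,branching_cap,branching_n_min
#'   branching experiment parameters.
#' @param calcium_animals,calcium_cells calcium experiment cohort size.
#' @param seed RNG seed recorded with every run, default 1.
#' @param out_dir optional output directory; when set, runners write the
#'   result bundle there.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("excitatory", "balanced",
                                             "response-curve",
                                             "block-inhibition",
                                             "branching", "calcium"),
                              N = 200, sigma = 0.05, g_i = -1.5,
                              r0 = 10, rmax = 80,
                              tau_m = 50, tau_a = 300, dt = 1,
                              baseline = -20, amplitudes = c(30, 40, 50),
                              pulse_width = 1000, pulse_gap = 1000,
                              inhibition_factor = 0,
                              branching_m = 1, branching_trials = 1e5,
                              branching_cap = 1e4, branching_n_min = 10,
                              calcium_animals = 10, calcium_cells = 50,
                              seed = 1, out_dir = NULL) {
  experiment <- match.arg(experiment)
  cfg <- list(experiment = experiment, N = N, sigma = sigma, g_i = g_i,
              r0 = r0, rmax = rmax, tau_m = tau_m, tau_a = tau_a, dt = dt,
              baseline = baseline, amplitudes = amplitudes,
              pulse_width = pulse_width, pulse_gap = pulse_gap,
              inhibition_factor = inhibition_factor,
              branching_m = branching_m,
              branching_trials = branching_trials,
              branching_cap = branching_cap,
              branching_n_min = branching_n_min,
              calcium_animals = calcium_animals,
              calcium_cells = calcium_cells,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' @keywords internal
cfg_drive <- function(config)
  pulse_protocol(config$baseline, config$amplitudes,
                 config$pulse_width, config$pulse_gap, config$dt)

#' @keywords internal
finish_bundle <- function(bundle, config) {
  bundle$config <- config
  class(bundle) <- "experiment_bundle"
  if (!is.null(config$out_dir)) save_bundle(bundle, config$out_dir)
  bundle
}

#' Run the pure-excitatory (all-or-none) experiment
#'
#' Builds a truncated-Gaussian excitatory network, sets the adaptation
#' strength to the mean summed input weight, simulates the pulse
#' protocol, and summarizes the per-pulse peak-rate distributions. The
#' signature result: peak rates cluster in the top histogram bin
#' regardless of (suprathreshold) input size, and the population
#' response shuts off before the pulse ends.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_bundle`: `sim`, `peaks`, `stats` (per-pulse
#'   [peak_stats()]), `g_w`, `response` (per-pulse mean peak vs
#'   amplitude), `config`.
#' @export
run_excitatory <- function(config = experiment_config("excitatory")) {
  J <- make_excitatory_weights(config$N, config$sigma, config$seed)
  g_w <- adaptation_strength(J)
  params <- network_params(config$N, config$tau_m, config$tau_a, g_w)
  f <- rate_fn(config$r0, config$rmax)
  sim <- simulate_network(J, params, f, cfg_drive(config), config$dt)
  peaks <- peak_rates(sim)
  st <- peak_stats(peaks)
  resp <- data.frame(amplitude = config$amplitudes,
                     mean_peak = colMeans(peaks$peaks))
  finish_bundle(list(sim = sim, peaks = peaks, stats = st, g_w = g_w,
                     response = resp), config)
}

#' Run the balanced (graded) experiment
#'
#' Builds the excitatory-inhibitory network (half the neurons inhibitory,
#' columns scaled by g_i) with adaptation off (g_w = 0), simulates the
#' same pulse protocol, and summarizes the per-pulse peak-rate
#' distributions: broad, positively skewed, mode far below the ceiling,
#' with a mean response that grows with pulse amplitude.
#'
#' @param config an [experiment_config()].
#' @param inhibition_factor optional attenuation of inhibitory weights in
#'   \[0, 1\]; 1 (default) leaves the balanced network intact.
#' @return An `experiment_bundle` as in [run_excitatory()].
#' @export
run_balanced <- function(config = experiment_config("balanced"),
                         inhibition_factor = 1) {
  J <- make_ei_weights(config$N, config$sigma, config$g_i, config$seed)
  if (inhibition_factor < 1) J <- scale_inhibition(J, inhibition_factor)
  params <- network_params(config$N, config$tau_m, config$tau_a, g_w = 0)
  f <- rate_fn(config$r0, config$rmax)
  sim <- simulate_network(J, params, f, cfg_drive(config), config$dt)
  peaks <- peak_rates(sim)
  st <- peak_stats(peaks)
  resp <- data.frame(amplitude = config$amplitudes,
                     mean_peak = colMeans(peaks$peaks))
  finish_bundle(list(sim = sim, peaks = peaks, stats = st, g_w = 0,
                     response = resp), config)
}

#' Run the inhibition-block experiment
#'
#' The balanced network with its inhibitory weights attenuated by
#' `config$inhibition_factor` (default 0, a full block). With inhibition
#' removed the network becomes highly supercritical and reverts to the
#' all-or-none signature of the pure-excitatory architecture on the same
#' drive.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_bundle` as in [run_balanced()].
#' @export
run_block_inhibition <- function(config = experiment_config("block-inhibition")) {
  run_balanced(config, inhibition_factor = config$inhibition_factor)
}

#' Run the response-curve experiment
#'
#' One single-pulse simulation per amplitude for each architecture, on a
#' fixed network per architecture, yielding the population-mean peak rate
#' as a function of drive amplitude: flat at the ceiling for the
#' pure-excitatory network, graded and increasing for the balanced one.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_bundle`: `excitatory` and `balanced`
#'   data.frames from [response_curve()], plus `config`.
#' @export
run_response_curve <- function(config = experiment_config("response-curve")) {
  f <- rate_fn(config$r0, config$rmax)
  one_arch <- function(J, g_w) {
    params <- network_params(config$N, config$tau_m, config$tau_a, g_w)
    sims <- lapply(config$amplitudes, function(a) {
      d <- pulse_protocol(config$baseline, a, config$pulse_width,
                          config$pulse_gap, config$dt)
      simulate_network(J, params, f, d, config$dt)
    })
    response_curve(sims)
  }
  Je <- make_excitatory_weights(config$N, config$sigma, config$seed)
  Jb <- make_ei_weights(config$N, config$sigma, config$g_i, config$seed)
  finish_bundle(list(excitatory = one_arch(Je, adaptation_strength(Je)),
                     balanced = one_arch(Jb, 0)), config)
}

#' Run the branching (criticality) experiment
#'
#' Simulates an avalanche ensemble at `config$branching_m`, fits the
#' avalanche-size power-law exponent above `config$branching_n_min`, and
#' locates the criticality transition on a ratio grid straddling 1.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_bundle`: `ensemble`, `fit` (a `powerlaw_fit`),
#'   `transition` (a `critical_ratio`), `config`.
#' @export
run_branching <- function(config = experiment_config("branching")) {
  ens <- simulate_branching(config$branching_m, "poisson",
                            config$branching_trials, config$branching_cap,
                            seed = config$seed)
  fit <- fit_powerlaw_exponent(ens, config$branching_n_min)
  trans <- locate_critical_ratio(seed = config$seed + 1)
  finish_bundle(list(ensemble = ens, fit = fit, transition = trans), config)
}

#' Run the synthetic-calcium experiment
#'
#' Generates the default cohort (10 animals x 50 cells, lognormal
#' amplitudes) and performs the cohort skewness analysis.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_bundle`: `dataset`, `cohort` (per-animal
#'   statistics), `config`.
#' @export
run_calcium <- function(config = experiment_config("calcium")) {
  ds <- generate_calcium_dataset(config$calcium_animals,
                                 config$calcium_cells, seed = config$seed)
  finish_bundle(list(dataset = ds, cohort = cohort_skewness_analysis(ds)),
                config)
}

#' Dispatch an experiment by its configured name
#'
#' @param config an [experiment_config()].
#' @return The corresponding `experiment_bundle`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  switch(config$experiment,
         "excitatory" = run_excitatory(config),
         "balanced" = run_balanced(config),
         "response-curve" = run_response_curve(config),
         "block-inhibition" = run_block_inhibition(config),
         "branching" = run_branching(config),
         "calcium" = run_calcium(config))
}

#' Write an experiment bundle to a directory
#'
#' Every bundle gets `config.json` (the full resolved configuration
#' including the seed), `stats.json` (all non-simulation summaries), CSV
#' data files for trajectories / peaks / curves / ensembles present in
#' the bundle, and `log.txt`.
#'
#' @param bundle an `experiment_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stats <- list()
  log_lines <- c(sprintf("experiment: %s", cfg$experiment),
                 sprintf("seed: %d", cfg$seed))
  if (!is.null(bundle$sim)) {
    write_sim(bundle$sim, file.path(dir, "trajectories.csv"))
    utils::write.csv(as.data.frame(bundle$peaks),
                     file.path(dir, "peaks.csv"), row.names = FALSE)
    utils::write.csv(bundle$stats, file.path(dir, "peak_stats.csv"),
                     row.names = FALSE)
    stats$peak_stats <- bundle$stats
    stats$g_w <- bundle$g_w
    stats$response <- bundle$response
    sat <- colMeans(bundle$peaks$peaks >= 0.95 * bundle$peaks$ceiling)
    stats$saturated_fraction_per_pulse <- sat
    log_lines <- c(log_lines,
                   sprintf("saturated fraction per pulse: %s",
                           paste(signif(sat, 3), collapse = " ")))
  }
  if (!is.null(bundle$excitatory)) {
    utils::write.csv(bundle$excitatory,
                     file.path(dir, "response_excitatory.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$balanced,
                     file.path(dir, "response_balanced.csv"),
                     row.names = FALSE)
    stats$excitatory <- bundle$excitatory
    stats$balanced <- bundle$balanced
  }
  if (!is.null(bundle$ensemble)) {
    utils::write.csv(as.data.frame(bundle$ensemble),
                     file.path(dir, "avalanches.csv"), row.names = FALSE)
    stats$powerlaw <- unclass(bundle$fit)
    stats$transition <- list(estimate = bundle$transition$estimate,
                             survival = bundle$transition$survival)
  }
  if (!is.null(bundle$dataset)) {
    write_calcium_dataset(bundle$dataset, file.path(dir, "calcium"))
    utils::write.csv(bundle$cohort, file.path(dir, "cohort.csv"),
                     row.names = FALSE)
    stats$cohort <- bundle$cohort
    stats$mean_skew_linear <- attr(bundle$cohort, "mean_skew_linear")
    stats$mean_abs_skew_log <- attr(bundle$cohort, "mean_abs_skew_log")
  }
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  writeLines(log_lines, file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %s (seed %d)\n",
              x$config$experiment, x$config$seed))
  invisible(x)
}
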