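## Independent oracles used across tests. These deliberately avoid the
## package's own implementations.

## Discrete power-law sampler by inverse CDF: exact table up to table_max,
## continuous-tail inversion beyond (rounding bias negligible out there).
rdpl <- function(n, alpha, xmin, table_max = 1e5) {
  ks <- xmin:table_max
  p <- ks^(-alpha)
  tail_mass <- (table_max + 0.5)^(1 - alpha) / (alpha - 1)
  Z <- sum(p) + tail_mass
  cdf <- cumsum(p) / Z
  u <- stats::runif(n)
  out <- numeric(n)
  in_table <- u <= cdf[length(cdf)]
  out[in_table] <- ks[findInterval(u[in_table], cdf) + 1L]
  if (any(!in_table)) {
    ut <- u[!in_table]
    out[!in_table] <- round(((1 - ut) * (alpha - 1) * Z)^(1 / (1 - alpha)))
  }
  out
}

## Closed-form skewness of a lognormal with log-scale sd sigma.
lognormal_skewness <- function(sigma) {
  es <- exp(sigma^2)
  (es + 2) * sqrt(es - 1)
}

## A connectivity object with all-zero weights (decoupled neurons).
zero_connectivity <- function(N) {
  J <- make_excitatory_weights(N, sigma = 0.05, seed = 1)
  J$weights[] <- 0
  J
}

## Small, fast experiment configuration for structural tests.
small_config <- function(experiment, ...) {
  experiment_config(experiment, N = 100, amplitudes = c(30, 40),
                    pulse_width = 500, pulse_gap = 500, ...)
}
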