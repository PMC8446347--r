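#' Network parameters
#'
#' Parameter container for the rate dynamics. The membrane-like activity
#' variable x relaxes with time constant `tau_m` and the intrinsic
#' adaptation variable w with `tau_a`; `g_w` sets how strongly adaptation
#' feeds back as a negative input. In the balanced (E/I) architecture
#' adaptation is switched off (`g_w = 0`) and stabilization is provided by
#' recurrent inhibition instead.
#'
#' @param N neuron count (>= 2), default 200.
#' @param tau_m activity time constant (ms), default 50.
#' @param tau_a adaptation time constant (ms), default 300.
#' @param g_w adaptation strength (>= 0), default 0; for the
#'   pure-excitatory model use [adaptation_strength()].
#' @return An object of class `network_params`.
#' @export
network_params <- function(N = 200, tau_m = 50, tau_a = 300, g_w = 0) {
  if (!is.numeric(N) || N < 2 || N != round(N))
    stop("'N' must be an integer >= 2", call. = FALSE)
  if (tau_m <= 0 || tau_a <= 0) stop("time constants must be positive",
                                     call. = FALSE)
  if (!is.numeric(g_w) || length(g_w) != 1L || g_w < 0)
    stop("'g_w' must be a single nonnegative number", call. = FALSE)
  structure(list(N = as.integer(N), tau_m = tau_m, tau_a = tau_a, g_w = g_w),
            class = "network_params")
}

#' Integrate the network rate dynamics by forward Euler
#'
#' Advances the coupled system
#' \deqn{\tau_m \dot x_i = -x_i + \sum_j J_{ij}\,\phi(x_j) - g_w w_i + I_e(t)}
#' \deqn{\tau_a \dot w_i = -w_i + \phi(x_i)}
#' with explicit first-order Euler steps on the drive's duration. J\[i, j\]
#' is the weight from sender j onto receiver i, phi the saturating rate
#' function, and Ie(t) the common external drive. The integration is
#' deterministic given its inputs.
#'
#' By default the network starts in the silent holding state under the
#' initial drive value: `x0 = Ie(0)`, `w0 = phi(x0)`. (The origin x = w = 0
#' is *not* silent for these networks -- phi(0) > 0 -- and starting there
#' triggers a spurious onset burst in the supercritical architecture.)
#'
#' @param J a `connectivity` object; its dimension must equal `params$N`.
#' @param params a [network_params()] object.
#' @param f a [rate_fn()] object.
#' @param drive a `drive_signal`; integration runs on its time grid span.
#' @param dt Euler step (ms); must satisfy `dt < min(tau_m, tau_a)/5`.
#'   Default 1 ms (tau_m/50 at the default time constants).
#' @param x0 initial activity: scalar or length-N vector; `NULL` (default)
#'   uses the silent holding state `Ie(0)`.
#' @param w0 initial adaptation: scalar or length-N vector; `NULL` uses
#'   `phi(x0)`.
#' @return An object of class `rate_sim`: `times` (ms), matrices `x`, `w`,
#'   `r` (time x neuron, with `r = phi(x)` at every sample), the `drive`,
#'   `connectivity`, `params`, `f` and the connectivity `seed`.
#' @examples
#' J <- make_excitatory_weights(50, seed = 1)
#' p <- network_params(N = 50, g_w = adaptation_strength(J))
#' sim <- simulate_network(J, p, drive = pulse_protocol())
#' max(sim$r)
#' @export
simulate_network <- function(J, params = network_params(), f = rate_fn(),
                             drive, dt = 1, x0 = NULL, w0 = NULL) {
  stopifnot(inherits(J, "connectivity"), inherits(params, "network_params"),
            inherits(f, "rate_fn"), inherits(drive, "drive_signal"))
  N <- params$N
  if (nrow(J$weights) != N || ncol(J$weights) != N)
    stop(sprintf("connectivity is %d x %d but params$N = %d",
                 nrow(J$weights), ncol(J$weights), N), call. = FALSE)
  if (dt <= 0 || dt >= min(params$tau_m, params$tau_a) / 5)
    stop("'dt' must satisfy 0 < dt < min(tau_m, tau_a)/5", call. = FALSE)

  ## drive resampled onto the integration grid (constant within drive steps)
  t_end <- max(drive$times)
  times <- seq(0, t_end, by = dt)
  nt <- length(times)
  idx <- pmin(findInterval(times, drive$times), length(drive$values))
  Ie <- drive$values[idx]

  x <- if (is.null(x0)) rep(Ie[1], N) else rep_len(as.numeric(x0), N)
  w <- if (is.null(w0)) firing_rate(x, f) else rep_len(as.numeric(w0), N)
  if (any(!is.finite(x)) || any(!is.finite(w)))
    stop("initial conditions must be finite", call. = FALSE)

  W <- J$weights
  gw <- params$g_w
  am <- dt / params$tau_m
  aa <- dt / params$tau_a
  X <- matrix(NA_real_, nt, N)
  Wm <- matrix(NA_real_, nt, N)
  for (t in seq_len(nt)) {
    X[t, ] <- x
    Wm[t, ] <- w
    r <- firing_rate(x, f)
    x_new <- x + am * (-x + as.vector(W %*% r) - gw * w + Ie[t])
    w_new <- w + aa * (-w + r)
    if (any(!is.finite(x_new)) || any(!is.finite(w_new)))
      stop(sprintf(
        "non-finite state at step %d (t = %g ms): integration unstable at dt = %g",
        t, times[t], dt), call. = FALSE)
    x <- x_new
    w <- w_new
  }
  R <- firing_rate(X, f)
  structure(list(times = times, x = X, w = Wm, r = R, drive = drive,
                 connectivity = J, params = params, f = f, seed = J$seed),
            class = "rate_sim")
}

#' @export
print.rate_sim <- function(x, ...) {
  cat(sprintf(
    "<rate_sim> %d neurons, %d steps (%g..%g ms), g_w = %g, rate range %.3g..%.3g\n",
    ncol(x$r), length(x$times), min(x$times), max(x$times),
    x$params$g_w, min(x$r), max(x$r)))
  invisible(x)
}

#' Long-format data frame of a simulation
#'
#' @param x a `rate_sim`.
#' @param ... unused.
#' @return data.frame with columns `time`, `neuron_id`, `x`, `w`, `r`.
#' @export
as.data.frame.rate_sim <- function(x, ...) {
  N <- ncol(x$r)
  nt <- length(x$times)
  data.frame(time = rep(x$times, N),
             neuron_id = rep(seq_len(N), each = nt),
             x = as.vector(x$x), w = as.vector(x$w), r = as.vector(x$r))
}

#' Write a simulation result
#'
#' Trajectories go to a long-format CSV (`time, neuron_id, x, w, r`) and a
#' JSON summary (per-neuron peak rates, parameters, seed) to `<path>.json`.
#'
#' @param sim a `rate_sim`.
#' @param path CSV path.
#' @export
write_sim <- function(sim, path) {
  stopifnot(inherits(sim, "rate_sim"))
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  summary <- list(
    n_neurons = ncol(sim$r), n_steps = length(sim$times),
    peak_rates = apply(sim$r, 2, max),
    params = unclass(sim$params),
    rate_fn = unclass(sim$f),
    sigma = sim$connectivity$sigma, g_i = sim$connectivity$g_i,
    seed = sim$seed)
  jsonlite::write_json(summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
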