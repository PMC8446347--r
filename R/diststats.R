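#' Adjusted Fisher-Pearson sample skewness
#'
#' The standardized third moment with the small-sample adjustment
#' G1 = g1 * sqrt(n(n-1))/(n-2), where g1 = m3 / m2^(3/2) and mk are the
#' central sample moments. Translation-invariant and invariant under
#' positive rescaling.
#'
#' @param values numeric sample, n >= 3, nonzero variance.
#' @return Skewness (dimensionless).
#' @export
sample_skewness <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || any(!is.finite(values)))
    stop("need >= 3 finite values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("constant sample: skewness undefined", call. = FALSE)
  g1 <- mean((values - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Lognormal maximum-likelihood fit
#'
#' For a positive sample the MLE of the lognormal parameters is the mean
#' and (1/n-denominator) standard deviation of the logs. A Shapiro-Wilk
#' statistic on the logs is reported as a descriptive lognormality summary,
#' not used as a hard gate (the exact family underlying skewed firing-rate
#' distributions is an open question).
#'
#' @param values strictly positive sample, n >= 10.
#' @return A list of class `lognormal_fit`: `meanlog`, `sdlog`, `n`,
#'   `shapiro_log_w`, `shapiro_log_p` (Shapiro-Wilk on the logs; computed
#'   on a fixed-seed subsample of 5000 when n exceeds that), and
#'   `log_likelihood`.
#' @export
fit_lognormal <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 10) stop("need >= 10 values", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be finite and > 0", call. = FALSE)
  lx <- log(values)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma > 0) {
    sub <- if (n > 5000) lx[round(seq(1, n, length.out = 5000))] else lx
    sw <- stats::shapiro.test(sub)
    w <- unname(sw$statistic); p <- sw$p.value
  } else {
    w <- NA_real_; p <- NA_real_
  }
  ll <- if (sigma > 0) sum(stats::dlnorm(values, mu, sigma, log = TRUE))
        else Inf
  structure(list(meanlog = mu, sdlog = sigma, n = n,
                 shapiro_log_w = w, shapiro_log_p = p,
                 log_likelihood = ll),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> meanlog = %.4f, sdlog = %.4f (n = %d)\n",
              x$meanlog, x$sdlog, x$n))
  if (is.finite(x$shapiro_log_w))
    cat(sprintf("  Shapiro-Wilk on logs: W = %.4f, p = %.3g\n",
                x$shapiro_log_w, x$shapiro_log_p))
  invisible(x)
}

#' Per-neuron peak rates over time windows
#'
#' For each neuron and each window, the maximum of the rate trajectory over
#' that window. Windows default to the drive's pulse intervals, giving one
#' peak distribution per pulse.
#'
#' @param result a `rate_sim`.
#' @param windows list of `c(start, end)` intervals (ms) within the
#'   simulated span; `NULL` (default) uses [drive_windows()] of the
#'   simulation's drive.
#' @return An object of class `peak_dist`: `peaks` (neuron x window
#'   matrix), `ceiling` (r0 + rmax), `window_labels`, `windows`.
#' @export
peak_rates <- function(result, windows = NULL) {
  stopifnot(inherits(result, "rate_sim"))
  if (is.null(windows)) windows <- drive_windows(result$drive)
  if (length(windows) == 0) stop("no windows: the drive has no pulses and ",
                                 "none were supplied", call. = FALSE)
  t_min <- min(result$times); t_max <- max(result$times)
  peaks <- sapply(windows, function(wd) {
    if (length(wd) != 2 || wd[1] >= wd[2])
      stop("each window must be c(start, end) with start < end",
           call. = FALSE)
    sel <- result$times >= wd[1] & result$times <= wd[2]
    if (!any(sel) || wd[1] < t_min || wd[2] > t_max)
      stop("window outside the simulated span", call. = FALSE)
    apply(result$r[sel, , drop = FALSE], 2, max)
  })
  peaks <- matrix(peaks, ncol = length(windows))
  structure(list(peaks = peaks, ceiling = rate_ceiling(result$f),
                 window_labels = seq_along(windows), windows = windows),
            class = "peak_dist")
}

#' @export
print.peak_dist <- function(x, ...) {
  cat(sprintf("<peak_dist> %d neurons x %d window(s), ceiling %g\n",
              nrow(x$peaks), ncol(x$peaks), x$ceiling))
  invisible(x)
}

#' @export
as.data.frame.peak_dist <- function(x, ...) {
  data.frame(neuron_id = rep(seq_len(nrow(x$peaks)), ncol(x$peaks)),
             window = rep(x$window_labels, each = nrow(x$peaks)),
             peak = as.vector(x$peaks))
}

#' Distribution statistics of peak rates
#'
#' Per window: skewness of the peaks on linear and log scale, lognormal
#' MLE parameters, the histogram mode, and the fraction of peaks in the
#' top histogram bin. Histograms use `bins` equal-width bins over
#' (0, ceiling] on the linear scale (the mode is the center of the most
#' populated bin); the all-or-none architecture parks the mode in the top
#' bin while the balanced architecture leaves it near zero.
#'
#' @param pd a `peak_dist`.
#' @param bins number of histogram bins, default 30.
#' @return data.frame, one row per window: `window`, `n`, `mean_peak`,
#'   `skew_linear`, `skew_log`, `lognorm_mu`, `lognorm_sigma`,
#'   `mode_estimate`, `top_bin_frac`.
#' @export
peak_stats <- function(pd, bins = 30) {
  stopifnot(inherits(pd, "peak_dist"))
  breaks <- seq(0, pd$ceiling, length.out = bins + 1)
  rows <- lapply(seq_len(ncol(pd$peaks)), function(k) {
    p <- pd$peaks[, k]
    h <- graphics::hist(p, breaks = breaks, plot = FALSE)
    data.frame(window = pd$window_labels[k], n = length(p),
               mean_peak = mean(p),
               skew_linear = sample_skewness(p),
               skew_log = sample_skewness(log(p)),
               lognorm_mu = fit_lognormal(p)$meanlog,
               lognorm_sigma = fit_lognormal(p)$sdlog,
               mode_estimate = h$mids[which.max(h$counts)],
               top_bin_frac = mean(p > breaks[bins]))
  })
  do.call(rbind, rows)
}

#' Population response curve over drive amplitudes
#'
#' Summarizes how the population-mean peak rate grows with the drive: for
#' each simulation (one per pulse amplitude, same network throughout) the
#' mean over neurons of the peak rate in the pulse window. The
#' pure-excitatory architecture yields a flat curve pinned at the
#' saturation ceiling; the balanced architecture yields a graded,
#' increasing curve.
#'
#' @param results list of `rate_sim` objects over increasing drive
#'   amplitudes, all sharing the same connectivity. A simulation whose
#'   drive has no pulses contributes amplitude 0 with the peak taken over
#'   the second half of its span (the settled holding state).
#' @return data.frame: `amplitude`, `mean_peak`, `sd_peak`.
#' @export
response_curve <- function(results) {
  if (!is.list(results) || length(results) < 2 ||
      !all(vapply(results, inherits, logical(1), "rate_sim")))
    stop("'results' must be a list of >= 2 rate_sim objects", call. = FALSE)
  W0 <- results[[1]]$connectivity$weights
  for (s in results[-1])
    if (!identical(s$connectivity$weights, W0))
      stop("all simulations must share the same network", call. = FALSE)
  rows <- lapply(results, function(s) {
    if (nrow(s$drive$pulses) == 0) {
      amp <- 0
      sel <- s$times >= max(s$times) / 2
      peaks <- apply(s$r[sel, , drop = FALSE], 2, max)
    } else {
      amp <- max(s$drive$pulses$amplitude)
      peaks <- peak_rates(s)$peaks
      peaks <- peaks[, which.max(s$drive$pulses$amplitude)]
    }
    data.frame(amplitude = amp, mean_peak = mean(peaks),
               sd_peak = stats::sd(peaks))
  })
  out <- do.call(rbind, rows)
  out[order(out$amplitude), , drop = FALSE]
}
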