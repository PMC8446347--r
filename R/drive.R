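#' Pulsed external-drive protocol
#'
#' Builds the time-varying external input Ie(t): a constant negative holding
#' baseline with rectangular positive pulses riding on top of it (pulse
#' level = baseline + amplitude). The protocol starts with one leading gap,
#' then alternates pulse / gap, ending with a trailing gap.
#'
#' The negative baseline keeps a supercritical recurrent network silent;
#' pulses of increasing amplitude imitate a rhythmic drive. Note that the
#' ignition threshold of the pure-excitatory network sits slightly below
#' zero drive level, so pulses need not reach positive levels to be
#' suprathreshold; see the package vignette.
#'
#' @param baseline holding level, must be negative. Default -20.
#' @param amplitudes positive pulse amplitudes. Within a standard protocol
#'   they are nondecreasing; a decreasing list is permitted with a warning.
#'   Default `c(30, 40, 50)`.
#' @param width pulse duration (ms), default 1000.
#' @param gap inter-pulse gap (ms), default 1000.
#' @param dt sample step (ms), default 1.
#' @return A `drive_signal` object: `times`, `values`, `baseline`,
#'   `pulses` (data.frame: onset, duration, amplitude), `dt`.
#' @examples
#' d <- pulse_protocol()
#' range(d$values)  # -20 and -20 + 50
#' @export
pulse_protocol <- function(baseline = -20, amplitudes = c(30, 40, 50),
                           width = 1000, gap = 1000, dt = 1) {
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline >= 0)
    stop("'baseline' must be a single negative number", call. = FALSE)
  if (length(amplitudes) == 0L)
    stop("'amplitudes' must contain at least one pulse", call. = FALSE)
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0))
    stop("pulse amplitudes must be strictly positive", call. = FALSE)
  if (is.unsorted(amplitudes))
    warning("pulse amplitudes are not nondecreasing; ",
            "permitted for custom protocols")
  if (width <= 0 || gap <= 0 || dt <= 0)
    stop("'width', 'gap' and 'dt' must be positive", call. = FALSE)

  n_p <- length(amplitudes)
  onsets <- gap + (seq_len(n_p) - 1) * (width + gap)
  total <- gap + n_p * (width + gap)
  times <- seq(0, total, by = dt)
  values <- rep(baseline, length(times))
  for (k in seq_len(n_p)) {
    in_pulse <- times >= onsets[k] & times < onsets[k] + width
    values[in_pulse] <- baseline + amplitudes[k]
  }
  structure(list(times = times, values = values, baseline = baseline,
                 pulses = data.frame(onset = onsets, duration = width,
                                     amplitude = amplitudes),
                 dt = dt),
            class = "drive_signal")
}

#' Constant drive held at a fixed level
#'
#' A degenerate protocol with no pulses, used e.g. for the zero-amplitude
#' point of a response curve.
#'
#' @param level drive level (any real).
#' @param duration total duration (ms).
#' @param dt sample step (ms).
#' @return A `drive_signal` with an empty pulse table.
#' @export
constant_drive <- function(level, duration, dt = 1) {
  stopifnot(is.numeric(level), length(level) == 1L, duration > 0, dt > 0)
  times <- seq(0, duration, by = dt)
  structure(list(times = times, values = rep(level, length(times)),
                 baseline = level,
                 pulses = data.frame(onset = numeric(0), duration = numeric(0),
                                     amplitude = numeric(0)),
                 dt = dt),
            class = "drive_signal")
}

#' Pulse time windows of a drive protocol
#'
#' @param drive a `drive_signal`.
#' @return A list of `c(start, end)` intervals (ms), one per pulse.
#' @export
drive_windows <- function(drive) {
  stopifnot(inherits(drive, "drive_signal"))
  lapply(seq_len(nrow(drive$pulses)), function(k)
    c(drive$pulses$onset[k], drive$pulses$onset[k] + drive$pulses$duration[k]))
}

#' @export
print.drive_signal <- function(x, ...) {
  cat(sprintf("<drive_signal> %g..%g ms (dt %g), baseline %g, %d pulse(s)\n",
              min(x$times), max(x$times), x$dt, x$baseline, nrow(x$pulses)))
  if (nrow(x$pulses) > 0) print(x$pulses)
  invisible(x)
}

#' Write / read a drive signal as two-column CSV
#'
#' Columns `time`, `value`; the pulse table and baseline are stored in a
#' JSON sidecar so the round trip is lossless on the sample grid.
#'
#' @param drive a `drive_signal`.
#' @param path CSV path; sidecar at `<path>.json`.
#' @export
write_drive <- function(drive, path) {
  stopifnot(inherits(drive, "drive_signal"))
  utils::write.csv(data.frame(time = drive$times, value = drive$values),
                   path, row.names = FALSE)
  jsonlite::write_json(list(baseline = drive$baseline, dt = drive$dt,
                            pulses = drive$pulses),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_drive
#' @export
read_drive <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pulses <- as.data.frame(meta$pulses)
  if (nrow(pulses) == 0)
    pulses <- data.frame(onset = numeric(0), duration = numeric(0),
                         amplitude = numeric(0))
  structure(list(times = d$time, values = d$value, baseline = meta$baseline,
                 pulses = pulses, dt = meta$dt),
            class = "drive_signal")
}
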