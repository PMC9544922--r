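#' EMG trace objects
#'
#' An `emg_trace` is the elementary signal container of the package: a
#' vector of samples in millivolts, a sampling rate in Hz, and the time of
#' the first sample (`t0_ms`) expressed in milliseconds relative to an
#' alignment event (a stimulus for MEP sweeps, a trial start for MVC
#' trials). Negative `t0_ms` therefore means the trace starts before the
#' event.
#'
#' @param samples Numeric vector of samples, in mV. Must be finite.
#' @param fs Sampling rate in Hz, > 0.
#' @param t0_ms Time of the first sample in ms relative to the alignment
#'   event (default 0).
#' @return An object of class `emg_trace`.
#' @export
#' @examples
#' tr <- emg_trace(sin(seq(0, 1, length.out = 200)), fs = 200)
#' rectify(tr)
emg_trace <- function(samples, fs, t0_ms = 0) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("trace samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, t0_ms = as.numeric(t0_ms)),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> %d samples @ %g Hz, t0 = %g ms, range [%.4g, %.4g] mV\n",
              length(x$samples), x$fs, x$t0_ms,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Sample times of a trace in milliseconds
#' @param trace An `emg_trace`.
#' @return Numeric vector of times (ms) relative to the alignment event.
#' @export
trace_times_ms <- function(trace) {
  trace$t0_ms + (seq_along(trace$samples) - 1) / trace$fs * 1000
}

as_trace_like <- function(trace, samples) {
  trace$samples <- samples
  trace
}

#' Full-wave rectification
#'
#' Replaces every sample by its absolute value. Metadata (`fs`, `t0_ms`)
#' is unchanged. Idempotent.
#'
#' @param trace An `emg_trace`.
#' @return The rectified trace.
#' @export
rectify <- function(trace) {
  stopifnot(inherits(trace, "emg_trace"))
  as_trace_like(trace, abs(trace$samples))
}

#' Centred 5-point moving-average smoothing
#'
#' The classic 5-point smoothing step: each sample is replaced by the mean
#' of itself and its four nearest neighbours. Edges are handled by
#' reflection padding (mirror about the end samples), so the output has
#' the same length as the input and constants and interior linear ramps
#' pass through unchanged.
#'
#' @param trace An `emg_trace` with at least 5 samples.
#' @return The smoothed trace.
#' @export
smooth5 <- function(trace) {
  stopifnot(inherits(trace, "emg_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < 5L) stop("smooth5 requires at least 5 samples", call. = FALSE)
  xp <- c(x[3], x[2], x, x[n - 1], x[n - 2])
  cs <- cumsum(c(0, xp))
  y <- (cs[6:(n + 5)] - cs[1:n]) / 5
  as_trace_like(trace, y)
}

# Second-order-section (biquad) cascade for a digital Butterworth filter.
# Q values follow from the Butterworth pole angles; each biquad uses the
# standard bilinear-transform low/high-pass prototype. Returned as a list
# of lists with normalised b, a coefficients.
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order < 2 || order %% 2 != 0) {
    stop("filter order must be an even integer >= 2", call. = FALSE)
  }
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)",
                 cutoff_hz, fs / 2), call. = FALSE)
  }
  w0 <- 2 * pi * cutoff_hz / fs
  cw <- cos(w0); sw <- sin(w0)
  k <- seq_len(order / 2)
  Q <- 1 / (2 * sin((2 * k - 1) * pi / (2 * order)))
  lapply(Q, function(q) {
    alpha <- sw / (2 * q)
    b <- if (type == "low") {
      c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
    } else {
      c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
    }
    a <- c(1 + alpha, -2 * cw, 1 - alpha)
    list(b = b / a[1], a = a / a[1])
  })
}

# One biquad, direct form, zero initial state: convolution for the MA
# part, then the AR recursion (both in C via stats::filter).
biquad <- function(b, a, x) {
  v <- stats::filter(x, b, method = "convolution", sides = 1)
  v[1] <- b[1] * x[1]
  v[2] <- b[1] * x[2] + b[2] * x[1]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

# Zero-phase (forward-backward) application of an SOS cascade with
# reflection padding sized to several filter time constants.
sos_filtfilt <- function(sos, x, fs, cutoff_hz) {
  n <- length(x)
  np <- min(n - 1L, as.integer(ceiling(25 * fs / cutoff_hz)))
  if (np < 1L) stop("trace too short to filter", call. = FALSE)
  xx <- c(2 * x[1] - x[seq(np + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - np)])
  for (s in sos) xx <- biquad(s$b, s$a, xx)
  xx <- rev(xx)
  for (s in sos) xx <- biquad(s$b, s$a, xx)
  xx <- rev(xx)
  xx[(np + 1):(np + n)]
}

# Squared magnitude response |H|^2 of an SOS cascade at normalised
# angular frequencies w (radians per sample); equals the amplitude
# response of the zero-phase (two-pass) application of the cascade.
sos_gain2 <- function(sos, w) {
  z1 <- exp(-1i * w); z2 <- exp(-2i * w)
  g <- rep(1, length(w))
  for (s in sos) {
    g <- g * Mod((s$b[1] + s$b[2] * z1 + s$b[3] * z2) /
                   (1 + s$a[2] * z1 + s$a[3] * z2))^2
  }
  g
}

#' Zero-phase steep low-pass filter
#'
#' Applies a high-order Butterworth low-pass forward and backward
#' (zero-phase) so onset/offset timing is not skewed by filter delay. The
#' filter is realised as a cascade of second-order sections, which keeps
#' it numerically exact even at very low normalised cutoffs (230 Hz at a
#' 20 kHz sampling rate): a constant input passes with unit gain to
#' within 1e-6.
#'
#' @param trace An `emg_trace`.
#' @param cutoff_hz Cutoff frequency in Hz (default 230). Must be below
#'   the Nyquist frequency.
#' @param order Butterworth order of each pass (even, default 8; the
#'   two-pass magnitude response is the square of the one-pass response).
#' @return The filtered trace.
#' @export
lowpass <- function(trace, cutoff_hz = 230, order = 8) {
  stopifnot(inherits(trace, "emg_trace"))
  sos <- butter_sos(order, cutoff_hz, trace$fs, "low")
  as_trace_like(trace, sos_filtfilt(sos, trace$samples, trace$fs, cutoff_hz))
}

#' Zero-phase high-pass filter
#'
#' Companion to [lowpass()]; used by the synthetic-data generator to
#' band-limit background EMG.
#'
#' @inheritParams lowpass
#' @export
highpass <- function(trace, cutoff_hz, order = 4) {
  stopifnot(inherits(trace, "emg_trace"))
  sos <- butter_sos(order, cutoff_hz, trace$fs, "high")
  as_trace_like(trace, sos_filtfilt(sos, trace$samples, trace$fs, cutoff_hz))
}

#' DC-offset correction against a reference window
#'
#' Subtracts from the whole trace the mean of the samples falling inside
#' `ref_window_ms` (times relative to the alignment event), so that the
#' corrected trace has zero mean over the reference window.
#'
#' @param trace An `emg_trace`.
#' @param ref_window_ms Length-2 numeric `(start, end)` in ms; must
#'   contain at least one sample.
#' @return The offset-corrected trace.
#' @export
correct_dc <- function(trace, ref_window_ms) {
  stopifnot(inherits(trace, "emg_trace"))
  if (length(ref_window_ms) != 2L || ref_window_ms[2] <= ref_window_ms[1]) {
    stop("`ref_window_ms` must be (start, end) with end > start", call. = FALSE)
  }
  t <- trace_times_ms(trace)
  sel <- t >= ref_window_ms[1] & t <= ref_window_ms[2]
  if (!any(sel)) stop("DC reference window contains no samples", call. = FALSE)
  as_trace_like(trace, trace$samples - mean(trace$samples[sel]))
}

#' MEP preprocessing chain
#'
#' The conditioning applied to every MEP sweep before averaging, in this
#' order: full-wave rectification, 5-point smoothing, zero-phase low-pass
#' filtering, DC-offset correction against the pre-stimulus baseline
#' window. The order matters: rectifying a zero-mean trace before
#' filtering is not the same as filtering first (the MVC chain, by
#' contrast, filters first and then rectifies; see [quantify_mvc()]).
#'
#' @param trace An `emg_trace` (a raw stimulus-aligned sweep).
#' @param params Parameter list from [mep_params()].
#' @return The preprocessed trace. Note the result is not guaranteed
#'   non-negative: DC correction can push samples below zero.
#' @export
preprocess_mep <- function(trace, params = mep_params()) {
  tr <- rectify(trace)
  tr <- smooth5(tr)
  tr <- lowpass(tr, cutoff_hz = params$lowpass_hz, order = params$filter_order)
  correct_dc(tr, params$baseline_window_ms)
}

#' Default MEP/MVC analysis parameters
#'
#' @param lowpass_hz Low-pass cutoff in Hz (default 230).
#' @param filter_order Butterworth order per pass (default 8).
#' @param baseline_window_ms Pre-stimulus window (ms) used for the DC
#'   reference and the baseline estimate. Default `c(-45, -5)`.
#' @param search_window_ms Post-stimulus window (ms) searched for a
#'   response. Default `c(3, 100)` (starts at the blanking edge).
#' @param epoch_window_ms Sweep extent around each stimulus, default
#'   `c(-50, 100)` ms.
#' @param blank_ms Post-stimulus blanking interval (ms) replaced by the
#'   sweep's baseline mean, to exclude the stimulus artifact (default 3).
#' @param rel_criterion Relative deviation from baseline defining
#'   response onset/offset (default 0.15, i.e. 15 percent).
#' @param abs_floor_mV Absolute floor added to the baseline for the
#'   detection threshold, guarding the degenerate near-zero-baseline case
#'   and sized to about four times the residual noise SD of a 20-sweep
#'   average at the default background level (default 0.01 mV).
#' @param min_run_ms Minimum time the signal must stay above threshold to
#'   count as a response; longer than the correlation time of the 230 Hz
#'   low-pass so a single noise swing cannot qualify (default 3 ms).
#' @param n_select Number of cleanest sweeps averaged (default 20).
#' @param mvc_trials_per_limb Expected trials per limb in an MVC session
#'   (default 3).
#' @return A named list of parameters.
#' @export
mep_params <- function(lowpass_hz = 230,
                       filter_order = 8,
                       baseline_window_ms = c(-45, -5),
                       search_window_ms = c(3, 100),
                       epoch_window_ms = c(-50, 100),
                       blank_ms = 3,
                       rel_criterion = 0.15,
                       abs_floor_mV = 0.01,
                       min_run_ms = 3,
                       n_select = 20,
                       mvc_trials_per_limb = 3) {
  list(lowpass_hz = lowpass_hz, filter_order = filter_order,
       baseline_window_ms = baseline_window_ms,
       search_window_ms = search_window_ms,
       epoch_window_ms = epoch_window_ms, blank_ms = blank_ms,
       rel_criterion = rel_criterion, abs_floor_mV = abs_floor_mV,
       min_run_ms = min_run_ms, n_select = n_select,
       mvc_trials_per_limb = mvc_trials_per_limb)
}
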