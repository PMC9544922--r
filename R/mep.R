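#' Baseline level of a preprocessed trace
#'
#' Mean of the rectified preprocessed trace over a fully pre-stimulus
#' window; the reference level the onset/offset criterion is relative to.
#' Always non-negative.
#'
#' @param trace An `emg_trace` (normally a preprocessed sweep average).
#' @param pre_window_ms Length-2 window in ms, entirely pre-stimulus.
#' @return Baseline level in mV.
#' @export
estimate_baseline <- function(trace, pre_window_ms = c(-45, -5)) {
  stopifnot(inherits(trace, "emg_trace"))
  if (pre_window_ms[2] > 0) {
    stop("baseline window must be entirely pre-stimulus", call. = FALSE)
  }
  t <- trace_times_ms(trace)
  sel <- t >= pre_window_ms[1] & t <= pre_window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  mean(abs(trace$samples[sel]))
}

#' Detect response onset and offset
#'
#' A response is a sustained deviation of the signal above the baseline:
#' the detection threshold is `max(baseline * (1 + rel_criterion),
#' baseline + abs_floor_mV)`. The relative part implements the classic
#' "15 percent deviation from baseline" rule; the absolute floor guards
#' the degenerate case of a near-zero baseline, where a purely relative
#' criterion would fire on any noise. Onset is the first time the trace
#' exceeds the threshold for at least `min_run_ms`; offset is the end of
#' the last such run starting inside the search window.
#'
#' @param trace Preprocessed average `emg_trace`.
#' @param baseline_mV Baseline level (from [estimate_baseline()]).
#' @param rel_criterion Relative deviation criterion (default 0.15).
#' @param min_run_ms Minimum suprathreshold run length in ms (default 3).
#' @param search_window_ms Post-stimulus `(start, end)` window in ms.
#' @param abs_floor_mV Absolute threshold floor in mV (default 0.01).
#' @return List with `detected` (logical), `onset_ms`, `offset_ms`
#'   (NA when not detected) and `threshold_mV`.
#' @export
detect_onset_offset <- function(trace, baseline_mV,
                                rel_criterion = 0.15,
                                min_run_ms = 3,
                                search_window_ms = c(3, 100),
                                abs_floor_mV = 0.01) {
  stopifnot(inherits(trace, "emg_trace"))
  if (baseline_mV < 0) stop("baseline must be >= 0", call. = FALSE)
  if (length(search_window_ms) != 2L ||
      search_window_ms[2] <= search_window_ms[1] || search_window_ms[1] < 0) {
    stop("invalid post-stimulus search window", call. = FALSE)
  }
  thr <- max(baseline_mV * (1 + rel_criterion), baseline_mV + abs_floor_mV)
  t <- trace_times_ms(trace)
  sel <- which(t >= search_window_ms[1] & t <= search_window_ms[2])
  if (!length(sel)) stop("search window contains no samples", call. = FALSE)
  above <- trace$samples[sel] > thr
  none <- list(detected = FALSE, onset_ms = NA_real_, offset_ms = NA_real_,
               threshold_mV = thr)
  if (!any(above)) return(none)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_run <- max(1L, ceiling(min_run_ms / 1000 * trace$fs))
  ok <- which(r$values & r$lengths >= min_run)
  if (!length(ok)) return(none)
  onset <- t[sel[starts[ok[1]]]]
  offset <- t[sel[ends[ok[length(ok)]]]]
  list(detected = TRUE, onset_ms = onset, offset_ms = offset,
       threshold_mV = thr)
}

#' Area under the curve between response bounds
#'
#' Trapezoidal integral of the trace between onset and offset, in
#' mV * ms. Non-negative whenever the trace is non-negative on the
#' interval.
#'
#' @param trace An `emg_trace`.
#' @param onset_ms,offset_ms Bounds in ms, `onset_ms <= offset_ms`, both
#'   inside the trace extent.
#' @return AUC in mV*ms.
#' @export
compute_auc <- function(trace, onset_ms, offset_ms) {
  stopifnot(inherits(trace, "emg_trace"))
  if (onset_ms > offset_ms) stop("onset must not exceed offset", call. = FALSE)
  t <- trace_times_ms(trace)
  if (onset_ms < t[1] - 1e-9 || offset_ms > t[length(t)] + 1e-9) {
    stop("integration bounds outside trace extent", call. = FALSE)
  }
  sel <- t >= onset_ms & t <= offset_ms
  trapz(t[sel], trace$samples[sel])
}

#' Quantify an averaged, preprocessed MEP trace
#'
#' Composes baseline estimation, onset/offset detection, AUC and
#' duration into one `mep_result`. An undetected response yields zero
#' AUC and duration.
#'
#' @param avg_trace Preprocessed sweep average (`emg_trace`).
#' @param params Parameters from [mep_params()].
#' @param n_sweeps_used Number of sweeps behind the average (metadata).
#' @return An object of class `mep_result`: list with `baseline_mV`,
#'   `detected`, `onset_ms`, `offset_ms`, `duration_ms`, `auc_mVms`,
#'   `threshold_mV`, `n_sweeps_used`.
#' @export
quantify_mep <- function(avg_trace, params = mep_params(),
                         n_sweeps_used = NA_integer_) {
  baseline <- estimate_baseline(avg_trace, params$baseline_window_ms)
  det <- detect_onset_offset(avg_trace, baseline,
                             rel_criterion = params$rel_criterion,
                             min_run_ms = params$min_run_ms,
                             search_window_ms = params$search_window_ms,
                             abs_floor_mV = params$abs_floor_mV)
  auc <- 0; dur <- 0
  if (det$detected) {
    auc <- compute_auc(avg_trace, det$onset_ms, det$offset_ms)
    dur <- det$offset_ms - det$onset_ms
  }
  structure(list(
    baseline_mV = baseline, detected = det$detected,
    onset_ms = det$onset_ms, offset_ms = det$offset_ms,
    duration_ms = dur, auc_mVms = auc,
    threshold_mV = det$threshold_mV,
    n_sweeps_used = n_sweeps_used
  ), class = "mep_result")
}

#' @export
print.mep_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "<mep_result> detected: onset %.2f ms, offset %.2f ms (duration %.2f ms), AUC %.4g mV*ms, baseline %.4g mV\n",
      x$onset_ms, x$offset_ms, x$duration_ms, x$auc_mVms, x$baseline_mV))
  } else {
    cat(sprintf("<mep_result> no response (baseline %.4g mV)\n", x$baseline_mV))
  }
  invisible(x)
}

#' Full MEP analysis of one session
#'
#' End-to-end wrapper: epoch stimulus-aligned sweeps, score and select
#' the cleanest `n_select`, condition each selected sweep
#' (rectify, smooth, low-pass, DC-correct), average, and quantify.
#'
#' @param session A `raw_session` of modality mep/recruitment.
#' @param channel Channel to analyse (default: first).
#' @param params Parameters from [mep_params()].
#' @return A `mep_result` (with attribute `"avg_trace"` holding the
#'   preprocessed average for plotting).
#' @export
analyze_mep_session <- function(session, channel = NULL,
                                params = mep_params()) {
  sw <- epoch_sweeps(session, channel = channel,
                     window_ms = params$epoch_window_ms,
                     blank_ms = params$blank_ms)
  k <- min(params$n_select, nrow(sw$sweeps))
  sw <- select_clean(sw, k = k)
  sw$sweeps <- sw$sweeps[sw$selected, , drop = FALSE]
  sw$cleanliness <- sw$cleanliness[sw$selected]
  sw$selected <- seq_len(nrow(sw$sweeps))
  sw <- preprocess_sweeps(sw, params)
  avg <- average_sweeps(sw)
  res <- quantify_mep(avg, params, n_sweeps_used = k)
  attr(res, "avg_trace") <- avg
  res
}

#' Threshold current from a recruitment series
#'
#' Given MEP results at strictly ascending stimulation currents, the
#' threshold is the smallest current with a detected response (the
#' minimal current producing an overt evoked contraction). Detection is
#' expected to be monotone in current; if a higher current shows no
#' response while a lower one does, the smallest detected current is
#' still returned, with a warning.
#'
#' @param series List of elements `list(current_mA =, result =)` where
#'   `result` is a `mep_result`, ordered by strictly ascending current.
#' @return Threshold current in mA, or `NA_real_` if no current evoked a
#'   response.
#' @export
find_threshold <- function(series) {
  cur <- vapply(series, function(e) e$current_mA, numeric(1))
  if (any(diff(cur) <= 0)) {
    stop("recruitment series must have strictly ascending currents",
         call. = FALSE)
  }
  det <- vapply(series, function(e) isTRUE(e$result$detected), logical(1))
  if (!any(det)) return(NA_real_)
  first <- which(det)[1]
  if (any(!det[seq_along(det) > first])) {
    warning("non-monotone detection across currents; reporting smallest detected current",
            call. = FALSE)
  }
  cur[first]
}
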