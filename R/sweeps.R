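#' Stimulus-aligned sweep sets
#'
#' [epoch_sweeps()] cuts one stimulus-aligned epoch ("sweep") per
#' stimulus event out of a session, blanks the brief stimulus artifact,
#' and scores each sweep's pre-stimulus cleanliness. The study design
#' acquires more sweeps than it averages: the cleanest `k` are selected
#' with [select_clean()] (automating the traditional manual pick of
#' sweeps with minimal spontaneous EMG) and averaged with
#' [average_sweeps()] to cancel movement-related activity.
#'
#' @param session A `raw_session` of modality `"mep"` or `"recruitment"`.
#' @param channel Channel label to epoch (default: first channel).
#' @param window_ms Epoch extent `(pre, post)` in ms around each
#'   stimulus, default `c(-50, 100)`.
#' @param blank_ms Post-stimulus blanking interval in ms: samples in
#'   `[0, blank_ms]` are replaced by the sweep's pre-stimulus mean so the
#'   stimulus artifact cannot masquerade as a response (default 3).
#' @return A `sweep_set`: list with `sweeps` (matrix, one row per sweep),
#'   `fs`, `t0_ms`, `window_ms`, `cleanliness` (pre-stimulus rectified
#'   RMS per sweep, mV) and `selected` (indices, initially all sweeps).
#' @export
epoch_sweeps <- function(session, channel = NULL,
                         window_ms = c(-50, 100), blank_ms = 3) {
  stopifnot(inherits(session, "raw_session"))
  if (!session$modality %in% c("mep", "recruitment")) {
    stop("epoch_sweeps needs an mep or recruitment session", call. = FALSE)
  }
  channel <- channel %||% session$channels[1]
  if (!channel %in% session$channels) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  x <- session$signal[, channel]
  fs <- session$fs
  n <- length(x)
  i_pre <- round(window_ms[1] / 1000 * fs)   # negative
  i_post <- round(window_ms[2] / 1000 * fs)
  len <- i_post - i_pre + 1L
  keep <- list(); skipped <- 0L
  for (ev in session$stim_events) {
    c0 <- round(ev * fs) + 1L            # sample index of stimulus
    a <- c0 + i_pre; b <- c0 + i_post
    if (a < 1L || b > n) { skipped <- skipped + 1L; next }
    keep[[length(keep) + 1L]] <- x[a:b]
  }
  if (skipped > 0L) {
    warning(sprintf("%d event(s) too close to the recording edge were skipped",
                    skipped), call. = FALSE)
  }
  if (!length(keep)) stop("no usable stimulus events in window", call. = FALSE)
  sweeps <- do.call(rbind, keep)
  t_ms <- window_ms[1] + (seq_len(len) - 1) / fs * 1000
  pre_idx <- which(t_ms < 0)
  # blanking: replace [0, blank_ms] by the sweep's pre-stimulus mean
  blank_idx <- which(t_ms >= 0 & t_ms <= blank_ms)
  if (length(blank_idx)) {
    base_mean <- rowMeans(sweeps[, pre_idx, drop = FALSE])
    sweeps[, blank_idx] <- base_mean
  }
  cleanliness <- sqrt(rowMeans(sweeps[, pre_idx, drop = FALSE]^2))
  structure(list(
    sweeps = sweeps, fs = fs, t0_ms = window_ms[1], window_ms = window_ms,
    cleanliness = cleanliness, selected = seq_len(nrow(sweeps))
  ), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g Hz, window [%g, %g] ms, %d selected\n",
              nrow(x$sweeps), ncol(x$sweeps), x$fs,
              x$window_ms[1], x$window_ms[2], length(x$selected)))
  invisible(x)
}

#' Select the cleanest sweeps
#'
#' Keeps the `k` sweeps with the smallest pre-stimulus rectified RMS
#' (spontaneous-activity score computed by [epoch_sweeps()]); ties are
#' broken in favour of earlier sweeps, so selection is deterministic.
#' Only pre-stimulus samples enter the score, so post-stimulus response
#' energy can never influence which sweeps are kept.
#'
#' @param sweeps A `sweep_set`.
#' @param k Number of sweeps to select (default 20).
#' @return The `sweep_set` with its `selected` field replaced.
#' @export
select_clean <- function(sweeps, k = 20) {
  stopifnot(inherits(sweeps, "sweep_set"))
  n <- nrow(sweeps$sweeps)
  if (k > n) stop(sprintf("cannot select %d of %d sweeps", k, n), call. = FALSE)
  ord <- order(sweeps$cleanliness, seq_len(n))   # stable: ties -> earlier index
  sweeps$selected <- sort(ord[seq_len(k)])
  sweeps
}

#' Average sweeps pointwise
#'
#' Arithmetic mean across the selected sweeps (or all sweeps). Averaging
#' n independent noise sweeps shrinks the background RMS roughly as
#' 1/sqrt(n) while a stimulus-locked response is preserved.
#'
#' @param sweeps A `sweep_set`.
#' @param use_selected Average only the selected subset (default TRUE).
#' @return An `emg_trace` aligned to the stimulus.
#' @export
average_sweeps <- function(sweeps, use_selected = TRUE) {
  stopifnot(inherits(sweeps, "sweep_set"))
  idx <- if (use_selected) sweeps$selected else seq_len(nrow(sweeps$sweeps))
  if (!length(idx)) stop("empty sweep selection", call. = FALSE)
  emg_trace(colMeans(sweeps$sweeps[idx, , drop = FALSE]),
            fs = sweeps$fs, t0_ms = sweeps$t0_ms)
}

#' Preprocess every sweep of a sweep set
#'
#' Applies the MEP conditioning chain ([preprocess_mep()]) to each sweep
#' individually. Rectification happens per sweep *before* averaging:
#' averaging raw zero-mean sweeps first would cancel the response
#' together with the noise.
#'
#' @param sweeps A `sweep_set`.
#' @param params Parameters from [mep_params()].
#' @return The `sweep_set` with conditioned sweeps.
#' @export
preprocess_sweeps <- function(sweeps, params = mep_params()) {
  stopifnot(inherits(sweeps, "sweep_set"))
  out <- sweeps$sweeps
  for (i in seq_len(nrow(out))) {
    tr <- emg_trace(out[i, ], fs = sweeps$fs, t0_ms = sweeps$t0_ms)
    out[i, ] <- preprocess_mep(tr, params)$samples
  }
  sweeps$sweeps <- out
  sweeps
}
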