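#' Extract timestamped grip trials from an MVC session
#'
#' Cuts one trace per trial event out of the channel matching the
#' trial's limb label (channel labels are expected to end in the limb
#' label, e.g. channel `biceps_R` for limb `R`).
#'
#' @param session A `raw_session` of modality `"mvc"`.
#' @return List of elements `list(limb =, trace =, grip_force =)`, one
#'   per trial event, in recording order.
#' @export
extract_trials <- function(session) {
  stopifnot(inherits(session, "raw_session"))
  if (session$modality != "mvc") stop("extract_trials needs an mvc session", call. = FALSE)
  te <- session$trial_events
  if (is.null(te) || !nrow(te)) stop("session has no trial events", call. = FALSE)
  if (any(te$end_s - te$start_s <= 0)) stop("trial of zero or negative duration", call. = FALSE)
  # overlapping windows on the same limb are a recording error
  for (lb in unique(te$limb)) {
    w <- te[te$limb == lb, , drop = FALSE]
    w <- w[order(w$start_s), , drop = FALSE]
    if (nrow(w) > 1 && any(w$start_s[-1] < w$end_s[-nrow(w)])) {
      stop("overlapping trial windows on limb ", lb, call. = FALSE)
    }
  }
  lapply(seq_len(nrow(te)), function(i) {
    limb <- te$limb[i]
    ch <- session$channels[endsWith(session$channels, limb)]
    if (length(ch) != 1L) {
      stop("no unique channel for limb '", limb, "'", call. = FALSE)
    }
    a <- round(te$start_s[i] * session$fs) + 1L
    b <- round(te$end_s[i] * session$fs)
    list(limb = limb,
         trace = emg_trace(session$signal[a:b, ch], fs = session$fs, t0_ms = 0),
         grip_force = te$grip_force[i])
  })
}

#' Quantify maximum voluntary contraction from a grip-task session
#'
#' Per trial, the raw channel trace is low-pass filtered first and the
#' timestamped portion is then rectified — note the order is the reverse
#' of the MEP chain, which rectifies before filtering — and the
#' trapezoidal AUC is taken over the full trial window. Trial AUCs are
#' averaged per limb, and the MVC value is the mean of the two limb
#' means. Grip-force readings are carried through as their own mean but
#' never enter the EMG quantification, so the dissociation between
#' apparatus force and muscle activity remains analysable.
#'
#' @param session A `raw_session` of modality `"mvc"`.
#' @param params Parameters from [mep_params()]; uses `lowpass_hz`,
#'   `filter_order` and `mvc_trials_per_limb`.
#' @param strict Require exactly `mvc_trials_per_limb` trials per limb
#'   (default TRUE).
#' @return An object of class `mvc_result`: list with `trial_aucs`
#'   (data.frame limb/auc_mVms/duration_ms/grip_force), `limb_means`,
#'   `mvc_mVms`, `grip_force`.
#' @export
quantify_mvc <- function(session, params = mep_params(), strict = TRUE) {
  stopifnot(inherits(session, "raw_session"))
  if (session$modality != "mvc") stop("quantify_mvc needs an mvc session", call. = FALSE)
  te <- session$trial_events
  cnt <- table(te$limb)
  if (strict && any(cnt != params$mvc_trials_per_limb)) {
    stop(sprintf("expected %d trials per limb, got: %s",
                 params$mvc_trials_per_limb,
                 paste(names(cnt), cnt, sep = "=", collapse = ", ")),
         call. = FALSE)
  }
  # filter each needed channel once, then cut/rectify/integrate per trial
  filtered <- list()
  for (limb in unique(te$limb)) {
    ch <- session$channels[endsWith(session$channels, limb)]
    if (length(ch) != 1L) stop("no unique channel for limb '", limb, "'", call. = FALSE)
    tr <- emg_trace(session$signal[, ch], fs = session$fs, t0_ms = 0)
    filtered[[limb]] <- lowpass(tr, cutoff_hz = params$lowpass_hz,
                                order = params$filter_order)$samples
  }
  rows <- lapply(seq_len(nrow(te)), function(i) {
    limb <- te$limb[i]
    a <- round(te$start_s[i] * session$fs) + 1L
    b <- round(te$end_s[i] * session$fs)
    y <- abs(filtered[[limb]][a:b])
    t_ms <- (seq_along(y) - 1) / session$fs * 1000
    data.frame(limb = limb,
               auc_mVms = trapz(t_ms, y),
               duration_ms = (te$end_s[i] - te$start_s[i]) * 1000,
               grip_force = te$grip_force[i])
  })
  trial_aucs <- do.call(rbind, rows)
  limb_means <- tapply(trial_aucs$auc_mVms, trial_aucs$limb, mean)
  structure(list(
    trial_aucs = trial_aucs,
    limb_means = limb_means,
    mvc_mVms = mean(limb_means),
    grip_force = mean(trial_aucs$grip_force)
  ), class = "mvc_result")
}

#' @export
print.mvc_result <- function(x, ...) {
  cat(sprintf("<mvc_result> MVC = %.4g mV*ms (limbs: %s), grip force %.3g\n",
              x$mvc_mVms,
              paste(names(x$limb_means), sprintf("%.4g", x$limb_means),
                    sep = "=", collapse = ", "),
              x$grip_force))
  invisible(x)
}
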