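#' Raw EMG session objects
#'
#' A `raw_session` bundles one acquisition: multi-channel differential EMG
#' sampled at `fs` Hz, together with the event timestamps the analysis is
#' aligned to. Three modalities are supported: `"mep"` (stimulus-evoked
#' responses, with stimulus-onset times and a stimulation current),
#' `"recruitment"` (an MEP session acquired at one current of an
#' ascending series) and `"mvc"` (grip-task trials with timestamped trial
#' windows and grip-force readings).
#'
#' Weeks are encoded numerically so they sort naturally: baseline is
#' `-1`, post-injury weeks are `1..11` and the terminal time point is
#' `12`. All stored times are in seconds; analysis functions report
#' milliseconds.
#'
#' @param session_id,animal_id Identifier strings.
#' @param group Treatment group, one of `"untreated"`, `"chabc_only"`,
#'   `"triple"`, `"stim_only"`, `"stim_rehab"`.
#' @param week Integer week code (baseline = -1, 1..11 post-injury,
#'   12 terminal).
#' @param modality `"mep"`, `"mvc"` or `"recruitment"`.
#' @param fs Sampling rate in Hz.
#' @param signal Numeric matrix, one column per channel, in mV.
#' @param channels Character vector of channel labels (e.g.
#'   `"biceps_R"`, `"biceps_L"`), one per column of `signal`.
#' @param stim_events Stimulus-onset times in seconds (mep/recruitment).
#' @param stim_current_mA Stimulation current in mA (mep/recruitment).
#' @param trial_events For mvc sessions, a data.frame with columns
#'   `start_s`, `end_s`, `limb`, `grip_force`.
#' @param truth Optional list of generator ground truth (kept in the
#'   sidecar for parameter-recovery tests; `NULL` for real data).
#' @return An object of class `raw_session`.
#' @seealso [validate_session()], [read_session()], [write_session()]
#' @export
raw_session <- function(session_id, animal_id, group, week, modality, fs,
                        signal, channels,
                        stim_events = numeric(),
                        stim_current_mA = NA_real_,
                        trial_events = NULL,
                        truth = NULL) {
  signal <- as.matrix(signal)
  colnames(signal) <- channels
  s <- structure(list(
    session_id = as.character(session_id),
    animal_id = as.character(animal_id),
    group = as.character(group),
    week = as.integer(week),
    modality = as.character(modality),
    fs = as.numeric(fs),
    channels = as.character(channels),
    signal = signal,
    stim_events = as.numeric(stim_events),
    stim_current_mA = as.numeric(stim_current_mA),
    trial_events = trial_events,
    truth = truth
  ), class = "raw_session")
  issues <- validate_session(s)
  if (length(issues)) {
    stop("invalid session:\n  - ", paste(issues, collapse = "\n  - "),
         call. = FALSE)
  }
  s
}

session_groups <- function() {
  c("untreated", "chabc_only", "triple", "stim_only", "stim_rehab")
}

#' @export
print.raw_session <- function(x, ...) {
  dur <- nrow(x$signal) / x$fs
  cat(sprintf("<raw_session> %s [%s] animal %s, group %s, week %d\n",
              x$session_id, x$modality, x$animal_id, x$group, x$week))
  cat(sprintf("  %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$signal), nrow(x$signal), x$fs, dur))
  if (x$modality %in% c("mep", "recruitment")) {
    cat(sprintf("  %d stimulus events, current %g mA\n",
                length(x$stim_events), x$stim_current_mA))
  } else {
    cat(sprintf("  %d trial events\n", nrow(x$trial_events)))
  }
  invisible(x)
}

#' Validate a session against its structural invariants
#'
#' Checks every invariant of the session data model and reports issues as
#' human-readable strings; an empty character vector means the session is
#' valid. This function never throws, whatever the field values.
#'
#' @param session An object to check (normally a `raw_session`).
#' @return Character vector of issue descriptions (empty if valid).
#' @export
validate_session <- function(session) {
  issues <- character()
  say <- function(...) issues <<- c(issues, sprintf(...))
  s <- unclass(session)
  if (!is.list(s)) return("session: not a list-like object")

  if (!length(s$modality) || !s$modality %in% c("mep", "mvc", "recruitment")) {
    say("modality: must be one of mep, mvc, recruitment (got '%s')",
        paste(s$modality, collapse = ","))
  }
  if (!length(s$group) || !s$group %in% session_groups()) {
    say("group: unknown group label '%s'", paste(s$group, collapse = ","))
  }
  fs_ok <- is.numeric(s$fs) && length(s$fs) == 1L && is.finite(s$fs) && s$fs > 0
  if (!fs_ok) say("fs: sampling rate must be a single positive number")

  sig_ok <- is.matrix(s$signal) && is.numeric(s$signal) && nrow(s$signal) > 0
  if (!sig_ok) {
    say("signal: must be a non-empty numeric matrix (channels in columns)")
  } else {
    if (length(s$channels) != ncol(s$signal)) {
      say("channels: %d labels for %d signal columns",
          length(s$channels), ncol(s$signal))
    }
    if (!ncol(s$signal)) say("signal: needs at least one channel")
  }
  dur <- if (sig_ok && fs_ok) nrow(s$signal) / s$fs else NA_real_

  if (identical(s$modality, "mep") || identical(s$modality, "recruitment")) {
    if (!length(s$stim_events)) {
      say("stim_events: %s sessions need at least one stimulus event",
          s$modality)
    }
    if (length(s$stim_events) && is.finite(dur) &&
        (any(s$stim_events < 0) || any(s$stim_events > dur))) {
      say("stim_events: event times must lie within [0, %.3f] s", dur)
    }
  }
  if (identical(s$modality, "mvc")) {
    te <- s$trial_events
    if (is.null(te) || !is.data.frame(te) || !nrow(te)) {
      say("trial_events: mvc sessions need at least one trial event")
    } else {
      need <- c("start_s", "end_s", "limb", "grip_force")
      if (!all(need %in% names(te))) {
        say("trial_events: missing columns %s",
            paste(setdiff(need, names(te)), collapse = ", "))
      } else {
        if (any(te$end_s <= te$start_s)) {
          say("trial_events: every trial must have end_s > start_s")
        }
        if (is.finite(dur) && (any(te$start_s < 0) || any(te$end_s > dur))) {
          say("trial_events: trial windows must lie within [0, %.3f] s", dur)
        }
      }
    }
  }
  issues
}

#' Write a session bundle to disk
#'
#' A session bundle is a directory holding a plain-text signal table
#' (`signal.csv`, column `time_s` followed by one column per channel, mV)
#' and a JSON sidecar (`session.json`) with the metadata and event
#' timestamps. Both are human-inspectable and language-neutral. The
#' numeric round trip through [read_session()] is lossless to better than
#' 1e-9 mV.
#'
#' @param session A valid `raw_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  issues <- validate_session(session)
  if (length(issues)) {
    stop("refusing to write invalid session:\n  - ",
         paste(issues, collapse = "\n  - "), call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(session$signal)
  tab <- data.table::data.table(time_s = (seq_len(n) - 1) / session$fs)
  for (j in seq_along(session$channels)) {
    data.table::set(tab, j = session$channels[j], value = session$signal[, j])
  }
  data.table::fwrite(tab, file.path(path, "signal.csv"))
  meta <- list(
    session_id = session$session_id,
    animal_id = session$animal_id,
    group = session$group,
    week = session$week,
    modality = session$modality,
    fs = session$fs,
    channels = as.list(session$channels),
    stim_events = session$stim_events,
    stim_current_mA = session$stim_current_mA,
    trial_events = session$trial_events,
    truth = session$truth
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]. Validates the reconstructed session and
#' fails with a descriptive error on missing files, metadata/signal
#' mismatches or invariant violations.
#'
#' @param path Bundle directory.
#' @return A `raw_session`.
#' @export
read_session <- function(path) {
  sig_file <- file.path(path, "signal.csv")
  meta_file <- file.path(path, "session.json")
  if (!file.exists(sig_file)) stop("missing signal file: ", sig_file, call. = FALSE)
  if (!file.exists(meta_file)) stop("missing metadata sidecar: ", meta_file, call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  tab <- data.table::fread(sig_file)
  channels <- as.character(meta$channels)
  if (!all(channels %in% names(tab))) {
    stop("metadata/signal mismatch: channels ",
         paste(setdiff(channels, names(tab)), collapse = ", "),
         " not found in signal file", call. = FALSE)
  }
  sig <- as.matrix(tab[, channels, with = FALSE])
  te <- meta$trial_events
  if (!is.null(te) && length(te)) te <- as.data.frame(te) else te <- NULL
  raw_session(
    session_id = meta$session_id, animal_id = meta$animal_id,
    group = meta$group, week = meta$week, modality = meta$modality,
    fs = meta$fs, signal = sig, channels = channels,
    stim_events = meta$stim_events %||% numeric(),
    stim_current_mA = meta$stim_current_mA %||% NA_real_,
    trial_events = te,
    truth = meta$truth
  )
}

#' Duration of a session in seconds
#' @param session A `raw_session`.
#' @return Duration in seconds.
#' @export
session_duration_s <- function(session) {
  nrow(session$signal) / session$fs
}
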