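#' Simulation configuration
#'
#' Bundles every knob of the synthetic EMG session generator. Defaults
#' emulate the chronic recording design: 20 kHz differential biceps EMG,
#' stimulus trains (5 biphasic pulses at 500 Hz, 0.2 ms width) delivered
#' every 2 s with 60 triggers acquired per MEP session (of which 20 are
#' later selected), grip-task MVC sessions of three ~8 s trials per
#' limb, and a longitudinal cohort of 3 groups x 6 animals followed from
#' baseline (week -1) through post-injury weeks 1-11.
#'
#' The MEP response model is a gamma-shaped envelope (default latency
#' 8 ms, duration 15 ms at the 10 percent width) multiplying a
#' band-limited carrier, riding on 20-1000 Hz Gaussian background EMG
#' (RMS 0.05 mV) with low-frequency movement-artifact bursts at a
#' Poisson rate of 0.1/s. Group-by-week effect profiles multiply the
#' evoked and voluntary burst amplitudes; the default profiles encode a
#' post-injury drop, a recovery rising from week 4 and plateauing from
#' week 6 in the triple-treatment group, and flat injured levels in the
#' comparison groups.
#'
#' @param fs Sampling rate, Hz.
#' @param n_triggers Stimuli acquired per MEP session.
#' @param isi_s Inter-stimulus interval, s.
#' @param train `list(n_pulses, rate_hz, width_ms)` stimulation train.
#' @param mep `list(latency_ms, amp_mV, dur_ms, carrier_hz, shape)`
#'   MEP burst model; `shape` is the gamma envelope shape parameter.
#' @param background `list(band, rms_mV)` background EMG model.
#' @param artifact `list(move_rate_hz, move_amp_mV, move_dur_s,
#'   move_band, stim_amp_mV, stim_dur_ms)` artifact model.
#' @param mvc `list(n_trials, trial_s, gap_s, burst_frac, amp_mV,
#'   grip_mean, grip_cv, grip_shared)` grip-task model.
#' @param group_profiles Named list: group -> named numeric vector of
#'   per-week amplitude multipliers (names are week codes).
#' @param threshold_mA Baseline per-animal stimulation threshold, mA.
#' @param threshold_cv Log-normal coefficient of variation of per-animal
#'   thresholds in cohorts.
#' @param current_grid Ascending currents (mA) for recruitment series.
#' @param n_animals Animals per group in cohorts.
#' @param groups Groups simulated in cohorts.
#' @param weeks Week codes simulated in cohorts (baseline = -1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 20000,
                       n_triggers = 60,
                       isi_s = 2,
                       train = list(n_pulses = 5, rate_hz = 500, width_ms = 0.2),
                       mep = list(latency_ms = 8, amp_mV = 0.5, dur_ms = 15,
                                  carrier_hz = 400, shape = 4),
                       background = list(band = c(20, 1000), rms_mV = 0.05),
                       artifact = list(move_rate_hz = 0.1, move_amp_mV = 0.3,
                                       move_dur_s = 0.5, move_band = c(2, 10),
                                       stim_amp_mV = 5, stim_dur_ms = 1),
                       mvc = list(n_trials = 3, trial_s = 8, gap_s = 4,
                                  burst_frac = 0.7, amp_mV = 0.5,
                                  grip_mean = 700, grip_cv = 0.12,
                                  grip_shared = 0.15),
                       group_profiles = default_group_profiles(),
                       threshold_mA = 1.0,
                       threshold_cv = 0.15,
                       current_grid = seq(0.25, 3, by = 0.25),
                       n_animals = 6,
                       groups = c("untreated", "chabc_only", "triple"),
                       weeks = c(-1, 1:11)) {
  cfg <- list(fs = fs, n_triggers = n_triggers, isi_s = isi_s, train = train,
              mep = mep, background = background, artifact = artifact,
              mvc = mvc, group_profiles = group_profiles,
              threshold_mA = threshold_mA, threshold_cv = threshold_cv,
              current_grid = current_grid, n_animals = n_animals,
              groups = groups, weeks = weeks)
  stopifnot(fs > 0, n_triggers >= 1, isi_s > 0,
            background$rms_mV >= 0, mep$amp_mV >= 0, mvc$amp_mV >= 0,
            artifact$move_rate_hz >= 0, threshold_mA >= 0)
  for (g in groups) {
    prof <- group_profiles[[g]]
    if (is.null(prof) || !all(as.character(weeks) %in% names(prof))) {
      stop("group_profiles must define every simulated week for group ", g,
           call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default group-by-week effect profiles
#'
#' Amplitude multipliers relative to baseline. All groups share the
#' baseline level (1.0) and the acute post-injury drop; the
#' triple-treatment profile rises from week 4 and plateaus at 1.0 from
#' week 6 onwards, while untreated and single-treatment profiles stay
#' near the injured level.
#'
#' @param flat If TRUE, return all-ones profiles (a null cohort with no
#'   group or time effects), used for type-I-error calibration.
#' @return Named list of named numeric vectors (weeks -1, 1..12).
#' @export
default_group_profiles <- function(flat = FALSE) {
  wk <- c(-1, 1:12)
  mk <- function(v) stats::setNames(v, as.character(wk))
  if (flat) {
    one <- mk(rep(1, length(wk)))
    return(list(untreated = one, chabc_only = one, triple = one,
                stim_only = one, stim_rehab = one))
  }
  list(
    untreated  = mk(c(1.00, rep(0.40, 12))),
    chabc_only = mk(c(1.00, 0.40, rep(0.45, 11))),
    triple     = mk(c(1.00, 0.40, 0.42, 0.46, 0.60, 0.82,
                      rep(1.00, 7))),
    stim_only  = mk(c(1.00, rep(0.42, 12))),
    stim_rehab = mk(c(1.00, 0.40, 0.45, 0.50, 0.55, 0.62,
                      rep(0.70, 7)))
  )
}

profile_multiplier <- function(cfg, group, week) {
  prof <- cfg$group_profiles[[group]]
  if (is.null(prof)) stop("no effect profile for group ", group, call. = FALSE)
  m <- prof[as.character(week)]
  if (is.na(m)) stop("week ", week, " not in the effect profile of ", group,
                     call. = FALSE)
  unname(m)
}

# Band-limited unit-RMS Gaussian noise, synthesised in the frequency
# domain: a white-noise spectrum is shaped by the zero-phase amplitude
# response of the band-limiting Butterworth cascade (spectrally identical
# to forward-backward filtering, without the per-trace filtering cost).
# Exact-RMS normalised so analytic expectations based on the nominal RMS
# hold per realisation.
band_noise <- function(n, fs, band, order = 4) {
  w <- 2 * pi * (seq_len(n) - 1) / n
  wf <- pmin(w, 2 * pi - w)          # fold to [0, pi]
  A <- rep(1, n)
  hi <- min(band[2], 0.45 * fs)
  if (band[1] > 0) {
    A <- A * sos_gain2(butter_sos(order, band[1], fs, "high"), wf)
  }
  A <- A * sos_gain2(butter_sos(order, hi, fs, "low"), wf)
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * A, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Variance pass-ratio of the analysis low-pass applied to band-limited
# noise: computed deterministically from squared impulse responses of the
# zero-phase filter chains. Memoised (pure function of its arguments).
.var_ratio_cache <- new.env(parent = emptyenv())

lowpass_var_ratio <- function(fs, band, cutoff_hz, order_band = 4,
                              order_lp = 8) {
  key <- paste(fs, band[1], band[2], cutoff_hz, order_band, order_lp,
               sep = "|")
  hit <- .var_ratio_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- 8192
  imp <- c(rep(0, n / 2), 1, rep(0, n / 2 - 1))
  hi <- min(band[2], 0.45 * fs)
  h <- imp
  if (band[1] > 0) {
    h <- sos_filtfilt(butter_sos(order_band, band[1], fs, "high"), h, fs, band[1])
  }
  h <- sos_filtfilt(butter_sos(order_band, hi, fs, "low"), h, fs, hi)
  h2 <- sos_filtfilt(butter_sos(order_lp, cutoff_hz, fs, "low"), h, fs, cutoff_hz)
  out <- sum(h2^2) / sum(h^2)
  .var_ratio_cache[[key]] <- out
  out
}

# Gamma-shaped burst envelope, peak-normalised to 1. `dur_ms` is the
# width at 10 percent of the peak (approximately dur = 7*theta at
# shape 4). Zero before `latency_ms`.
gamma_envelope <- function(t_ms, latency_ms, dur_ms, shape = 4) {
  theta <- dur_ms / 7
  x <- (t_ms - latency_ms)
  xm <- (shape - 1) * theta
  env <- numeric(length(t_ms))
  pos <- x > 0
  env[pos] <- (x[pos] / xm)^(shape - 1) * exp((xm - x[pos]) / theta)
  env
}

# Expected rectified cycle-mean of carrier burst plus Gaussian noise:
# for A >= 0 and noise sd sigma, averages E|A sin(phi) + N(0, sigma)|
# over the carrier phase. Vectorised over A.
rect_cycle_mean <- function(A, sigma, n_phi = 64) {
  if (sigma <= 0) return(2 / pi * A)
  phi <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  sapply(A, function(a) {
    m <- a * sin(phi)
    mean(m * (2 * stats::pnorm(m / sigma) - 1) +
           2 * sigma * stats::dnorm(m / sigma))
  })
}

# Deterministic estimate of the residual baseline level of a noise-only
# preprocessed sweep average (internal fixed-seed Monte Carlo; enters
# only the ground-truth detection threshold).
expected_resid_baseline <- function(cfg, n_sel, params, seed) {
  fs <- cfg$fs
  win <- params$epoch_window_ms
  n <- round((win[2] - win[1]) / 1000 * fs) + 1L
  with_seed(derive_seed(seed, "truth-baseline"), {
    acc <- 0
    n_rep <- 8L
    for (r in seq_len(n_rep)) {
      sweeps <- matrix(0, n_sel, n)
      for (i in seq_len(n_sel)) {
        x <- band_noise(n, fs, cfg$background$band) * cfg$background$rms_mV
        tr <- emg_trace(x, fs = fs, t0_ms = win[1])
        sweeps[i, ] <- preprocess_mep(tr, params)$samples
      }
      avg <- emg_trace(colMeans(sweeps), fs = fs, t0_ms = win[1])
      acc <- acc + estimate_baseline(avg, params$baseline_window_ms)
    }
    acc / n_rep
  })
}

# Closed-form expected preprocessed MEP average and its ground-truth
# onset/offset/AUC under the detection rule.
mep_truth <- function(cfg, amp_eff, params, seed) {
  sigma <- cfg$background$rms_mV
  if (amp_eff <= 0) {
    return(list(amp_eff = 0, true_onset_ms = NA_real_,
                true_offset_ms = NA_real_, true_auc_mVms = 0,
                expected_baseline_mV = NA_real_, detectable = FALSE))
  }
  n_sel <- min(params$n_select, cfg$n_triggers)
  b_hat <- if (sigma > 0) expected_resid_baseline(cfg, n_sel, params, seed) else 0
  thr <- max(b_hat * (1 + params$rel_criterion), b_hat + params$abs_floor_mV)
  t <- seq(params$search_window_ms[1], params$search_window_ms[2], by = 0.01)
  A <- amp_eff * gamma_envelope(t, cfg$mep$latency_ms, cfg$mep$dur_ms,
                                cfg$mep$shape)
  mu <- rect_cycle_mean(A, sigma) - (if (sigma > 0) sigma * sqrt(2 / pi) else 0)
  above <- mu > thr
  if (!any(above)) {
    return(list(amp_eff = amp_eff, true_onset_ms = NA_real_,
                true_offset_ms = NA_real_, true_auc_mVms = 0,
                expected_baseline_mV = b_hat, detectable = FALSE))
  }
  i1 <- which(above)[1]; i2 <- which(above)[sum(above)]
  interp <- function(i_hi, i_lo) {
    # linear interpolation of the threshold crossing between grid points
    if (i_lo < 1 || i_lo > length(t)) return(t[i_hi])
    t[i_lo] + (thr - mu[i_lo]) / (mu[i_hi] - mu[i_lo]) * (t[i_hi] - t[i_lo])
  }
  onset <- if (i1 > 1) interp(i1, i1 - 1) else t[i1]
  offset <- if (i2 < length(t)) interp(i2, i2 + 1) else t[i2]
  sel <- t >= onset & t <= offset
  list(amp_eff = amp_eff,
       true_onset_ms = onset, true_offset_ms = offset,
       true_auc_mVms = trapz(t[sel], mu[sel]),
       expected_baseline_mV = b_hat, detectable = TRUE)
}

add_movement_artifacts <- function(x, fs, art) {
  dur_s <- length(x) / fs
  n_art <- stats::rpois(1, art$move_rate_hz * dur_s)
  if (n_art > 0) {
    for (i in seq_len(n_art)) {
      start <- stats::runif(1, 0, max(0, dur_s - art$move_dur_s))
      n_a <- max(8L, round(art$move_dur_s * fs))
      a <- round(start * fs) + 1L
      b <- min(length(x), a + n_a - 1L)
      w <- band_noise(n_a, fs, art$move_band, order = 2) *
        0.5 * (1 - cos(2 * pi * seq_len(n_a) / (n_a + 1)))
      x[a:b] <- x[a:b] + art$move_amp_mV * w[seq_len(b - a + 1L)]
    }
  }
  x
}

#' Simulate one MEP session
#'
#' Generates a two-channel differential biceps recording with
#' `cfg$n_triggers` stimulus events. If `current_mA` reaches the
#' animal's threshold, each stimulus is followed (on the contralateral
#' channel `biceps_R`) by a phase-locked MEP burst whose amplitude is
#' the configured burst amplitude times the group-week multiplier times
#' a recruitment gain `min(current/threshold, 2)`; below threshold no
#' burst is evoked. A brief high-amplitude artifact marks each stimulus
#' onset, and low-frequency movement bursts contaminate both channels at
#' a Poisson rate. Ground truth (effective amplitude, expected
#' onset/offset/AUC under the detection rule) is stored in the session's
#' `truth` field. Fully reproducible for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param animal_id,group,week Session identity; `week` must be in
#'   `cfg$weeks`.
#' @param current_mA Stimulation current, >= 0.
#' @param seed Integer seed.
#' @param threshold_mA Animal threshold (default `cfg$threshold_mA`).
#' @param params Analysis parameters ([mep_params()]); used only to
#'   define the ground-truth detection threshold stored in `truth`.
#' @param detail_truth Compute the (slightly costly) expected-trace
#'   ground truth (default TRUE).
#' @return A `raw_session` of modality `"mep"`.
#' @export
simulate_mep_session <- function(cfg, animal_id, group, week, current_mA,
                                 seed, threshold_mA = cfg$threshold_mA,
                                 params = mep_params(),
                                 detail_truth = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (current_mA < 0) stop("current must be >= 0", call. = FALSE)
  if (!week %in% cfg$weeks) stop("week ", week, " not in cfg$weeks", call. = FALSE)
  mult <- profile_multiplier(cfg, group, week)
  fs <- cfg$fs
  pre_s <- 0.25
  dur_s <- pre_s + cfg$n_triggers * cfg$isi_s + 0.25
  n <- round(dur_s * fs)
  events <- pre_s + (seq_len(cfg$n_triggers) - 1) * cfg$isi_s

  supra <- current_mA >= threshold_mA && threshold_mA > 0
  amp_eff <- if (supra) {
    cfg$mep$amp_mV * mult * min(current_mA / threshold_mA, 2)
  } else 0

  session <- with_seed(derive_seed(seed, animal_id, week, round(current_mA * 1000)), {
    sig <- matrix(0, n, 2)
    for (ch in 1:2) {
      x <- band_noise(n, fs, cfg$background$band) * cfg$background$rms_mV
      x <- add_movement_artifacts(x, fs, cfg$artifact)
      sig[, ch] <- x
    }
    # stimulus artifact: one biphasic transient at train onset, both channels
    n_a <- max(2L, round(cfg$artifact$stim_dur_ms / 1000 * fs))
    art_wave <- cfg$artifact$stim_amp_mV * sin(2 * pi * seq_len(n_a) / n_a)
    # phase-locked MEP burst on the contralateral channel
    if (amp_eff > 0) {
      n_b <- round((cfg$mep$latency_ms + 6 * cfg$mep$dur_ms) / 1000 * fs)
      tb <- (seq_len(n_b) - 1) / fs * 1000
      burst <- amp_eff * gamma_envelope(tb, cfg$mep$latency_ms, cfg$mep$dur_ms,
                                        cfg$mep$shape) *
        sin(2 * pi * cfg$mep$carrier_hz * (tb - cfg$mep$latency_ms) / 1000)
    }
    for (ev in events) {
      a <- round(ev * fs) + 1L
      sig[a:(a + n_a - 1L), ] <- sig[a:(a + n_a - 1L), ] + art_wave
      if (amp_eff > 0) {
        b <- min(n, a + length(burst) - 1L)
        sig[a:b, 1] <- sig[a:b, 1] + burst[seq_len(b - a + 1L)]
      }
    }
    sig
  })

  truth <- list(threshold_mA = threshold_mA, multiplier = mult,
                current_mA = current_mA, amp_eff = amp_eff)
  if (detail_truth) {
    det <- mep_truth(cfg, amp_eff, params, seed)
    truth <- c(truth, det[setdiff(names(det), "amp_eff")])
  }
  raw_session(
    session_id = sprintf("%s_w%+d_mep_%gmA", animal_id, week, current_mA),
    animal_id = animal_id, group = group, week = week, modality = "mep",
    fs = fs, signal = session, channels = c("biceps_R", "biceps_L"),
    stim_events = events, stim_current_mA = current_mA, truth = truth
  )
}

#' Simulate one MVC (grip-task) session
#'
#' Three timestamped trials per limb (alternating limbs), each of
#' roughly the configured trial duration, with a voluntary-contraction
#' burst — amplitude-modulated band-limited EMG noise under a smooth
#' envelope covering `burst_frac` of the trial — on the active limb's
#' channel and background EMG elsewhere. Grip-force readings share only
#' a weak factor with the EMG amplitude multiplier, reproducing the
#' dissociation between apparatus force and muscle activity. The truth
#' field records the multiplier and the closed-form expected trial AUC.
#'
#' @inheritParams simulate_mep_session
#' @return A `raw_session` of modality `"mvc"`.
#' @export
simulate_mvc_session <- function(cfg, animal_id, group, week, seed,
                                 params = mep_params()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!week %in% cfg$weeks) stop("week ", week, " not in cfg$weeks", call. = FALSE)
  mult <- profile_multiplier(cfg, group, week)
  fs <- cfg$fs
  m <- cfg$mvc
  amp_eff <- m$amp_mV * mult
  slot_s <- m$trial_s + m$gap_s
  n_trials <- 2L * m$n_trials
  dur_s <- 0.5 + n_trials * slot_s
  n <- round(dur_s * fs)
  limbs <- rep(c("R", "L"), m$n_trials)
  starts <- 0.25 + (seq_len(n_trials) - 1) * slot_s
  ends <- starts + m$trial_s

  out <- with_seed(derive_seed(seed, animal_id, week, "mvc"), {
    sig <- matrix(0, n, 2)
    for (ch in 1:2) {
      x <- band_noise(n, fs, cfg$background$band) * cfg$background$rms_mV
      sig[, ch] <- add_movement_artifacts(x, fs, cfg$artifact)
    }
    n_t <- round(m$trial_s * fs)
    env <- mvc_envelope(n_t, m$burst_frac)
    for (i in seq_len(n_trials)) {
      ch <- if (limbs[i] == "R") 1L else 2L
      a <- round(starts[i] * fs) + 1L
      b <- a + n_t - 1L
      sig[a:b, ch] <- sig[a:b, ch] +
        amp_eff * env * band_noise(n_t, fs, cfg$background$band)
    }
    grip <- m$grip_mean * (1 + m$grip_shared * (mult - 1)) *
      (1 + stats::rnorm(n_trials, 0, m$grip_cv))
    list(sig = sig, grip = grip)
  })

  rho <- lowpass_var_ratio(fs, cfg$background$band, params$lowpass_hz,
                           order_lp = params$filter_order)
  t_ms <- (seq_len(round(m$trial_s * fs)) - 1) / fs * 1000
  env <- mvc_envelope(length(t_ms), m$burst_frac)
  sigma_t <- sqrt(rho * (cfg$background$rms_mV^2 + (amp_eff * env)^2))
  expected_auc <- trapz(t_ms, sqrt(2 / pi) * sigma_t)

  trial_events <- data.frame(start_s = starts, end_s = ends,
                             limb = limbs, grip_force = out$grip)
  raw_session(
    session_id = sprintf("%s_w%+d_mvc", animal_id, week),
    animal_id = animal_id, group = group, week = week, modality = "mvc",
    fs = fs, signal = out$sig, channels = c("biceps_R", "biceps_L"),
    trial_events = trial_events,
    truth = list(multiplier = mult, amp_eff = amp_eff,
                 expected_trial_auc_mVms = expected_auc,
                 expected_mvc_auc_mVms = expected_auc)
  )
}

# Smooth contraction envelope: raised-cosine ramps into a hold phase
# covering `burst_frac` of the trial, centred in the window.
mvc_envelope <- function(n, burst_frac) {
  env <- numeric(n)
  n_b <- round(burst_frac * n)
  a <- (n - n_b) %/% 2
  ramp <- max(4L, round(0.15 * n_b))
  core <- numeric(n_b)
  core[] <- 1
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  core[seq_len(ramp)] <- up
  core[n_b + 1 - seq_len(ramp)] <- up
  env[a + seq_len(n_b)] <- core
  env
}

#' Simulate a recruitment series over ascending currents
#'
#' One MEP session per grid current; sessions below the animal's
#' threshold contain no evoked burst, sessions at or above it do, so
#' [find_threshold()] on the analysed series recovers the configured
#' threshold to within one grid step.
#'
#' @inheritParams simulate_mep_session
#' @param current_grid Ascending currents in mA (default
#'   `cfg$current_grid`).
#' @return List of elements `list(current_mA =, session =)`.
#' @export
simulate_recruitment_series <- function(cfg, animal_id, group = "untreated",
                                        week = cfg$weeks[1], seed = 1,
                                        threshold_mA = cfg$threshold_mA,
                                        current_grid = cfg$current_grid,
                                        params = mep_params()) {
  if (!length(current_grid)) stop("empty current grid", call. = FALSE)
  if (any(diff(current_grid) <= 0)) {
    stop("current grid must be strictly ascending", call. = FALSE)
  }
  lapply(current_grid, function(cur) {
    list(current_mA = cur,
         session = simulate_mep_session(
           cfg, animal_id, group, week, cur,
           seed = derive_seed(seed, "recruit", round(cur * 1000)),
           threshold_mA = threshold_mA, params = params,
           detail_truth = FALSE))
  })
}

#' Simulate a longitudinal cohort
#'
#' Full factorial animals x weeks for the configured groups. Per animal,
#' a stimulation threshold is drawn once (log-normal around
#' `cfg$threshold_mA`); per week, the requested modalities are
#' simulated: `"mvc"` grip sessions and/or `"mep"` sessions at 1.5x the
#' animal's threshold (the suprathreshold condition used for the
#' longitudinal evoked comparisons). Returns the sessions (or writes
#' them as bundles when `dir` is given) together with a ground-truth
#' table of the per-animal per-week multipliers and expected AUCs for
#' parameter-recovery tests.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param modalities Subset of `c("mvc", "mep")`.
#' @param dir Optional directory: write each session as a bundle and
#'   return paths instead of objects (ground truth goes to `truth.csv`).
#' @param params Analysis parameters (for MEP ground truth).
#' @param detail_truth Compute expected-trace MEP ground truth per
#'   session (default FALSE: cohort-level recovery uses amplitudes and
#'   expected AUCs only).
#' @return List with `sessions` (list of `raw_session` or of paths) and
#'   `truth` (data.frame: animal_id, group, week, multiplier,
#'   threshold_mA, expected_mvc_auc_mVms).
#' @export
simulate_cohort <- function(cfg, seed, modalities = c("mvc", "mep"),
                            dir = NULL, params = mep_params(),
                            detail_truth = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  modalities <- match.arg(modalities, c("mvc", "mep"), several.ok = TRUE)
  sessions <- list()
  truth_rows <- list()
  for (g in cfg$groups) {
    for (i in seq_len(cfg$n_animals)) {
      aid <- sprintf("%s_%02d", g, i)
      thr <- with_seed(derive_seed(seed, "threshold", aid), {
        cfg$threshold_mA * exp(stats::rnorm(1, 0, cfg$threshold_cv))
      })
      for (wk in cfg$weeks) {
        mult <- profile_multiplier(cfg, g, wk)
        row <- list(animal_id = aid, group = g, week = wk,
                    multiplier = mult, threshold_mA = thr,
                    expected_mvc_auc_mVms = NA_real_)
        if ("mvc" %in% modalities) {
          s <- simulate_mvc_session(cfg, aid, g, wk,
                                    seed = derive_seed(seed, aid, wk, "mvc"),
                                    params = params)
          row$expected_mvc_auc_mVms <- s$truth$expected_mvc_auc_mVms
          sessions[[length(sessions) + 1L]] <- s
        }
        if ("mep" %in% modalities) {
          s <- simulate_mep_session(cfg, aid, g, wk,
                                    current_mA = 1.5 * thr,
                                    seed = derive_seed(seed, aid, wk, "mep"),
                                    threshold_mA = thr, params = params,
                                    detail_truth = detail_truth)
          sessions[[length(sessions) + 1L]] <- s
        }
        truth_rows[[length(truth_rows) + 1L]] <- as.data.frame(row)
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(sessions, function(s) {
      p <- file.path(dir, s$session_id)
      write_session(s, p)
      p
    }, character(1))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    return(list(sessions = as.list(paths), truth = truth))
  }
  list(sessions = sessions, truth = truth)
}

#' Simulate motor-neuron counts per spinal level
#'
#' Negative-binomial integer counts per animal per level around the
#' given level means (zero-mean levels always yield zero counts, like
#' the empty rostral and caudal segments of the biceps pool).
#'
#' @param level_means Named numeric vector of mean counts for levels
#'   C2..T2 (non-negative).
#' @param n_animals Number of animals to draw.
#' @param dispersion Negative-binomial size parameter (larger = closer
#'   to Poisson), default 5.
#' @param group Group label for the output table.
#' @param seed Integer seed.
#' @return Long-format count table (see [load_mn_counts()]).
#' @export
simulate_mn_counts <- function(level_means, n_animals, dispersion = 5,
                               group = "sim", seed = 1) {
  lv <- spinal_levels()
  if (!all(lv %in% names(level_means))) {
    stop("level_means must be named with levels C2..T2", call. = FALSE)
  }
  if (any(level_means < 0)) stop("level means must be >= 0", call. = FALSE)
  counts <- with_seed(derive_seed(seed, "mn", group), {
    vapply(lv, function(l) {
      mu <- level_means[[l]]
      if (mu == 0) rep(0L, n_animals)
      else as.integer(stats::rnbinom(n_animals, size = dispersion, mu = mu))
    }, integer(n_animals))
  })
  counts <- matrix(counts, nrow = n_animals,
                   dimnames = list(NULL, lv))
  data.frame(
    animal_id = rep(sprintf("%s_%03d", group, seq_len(n_animals)),
                    each = length(lv)),
    group = group,
    level = factor(rep(lv, n_animals), levels = lv),
    count = as.integer(t(counts)),
    stringsAsFactors = FALSE
  )
}
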