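# Scaled-down simulation configurations used throughout the suite: the
# signal model and analysis chain are identical to the defaults, only
# sampling rate, trigger counts and trial durations are reduced so the
# suite stays fast. The vignette documents the problem sizes.

scaled_mep_cfg <- function(fs = 4000, n_triggers = 12, isi_s = 0.2,
                           rms_mV = 0.05, ...) {
  sim_config(fs = fs, n_triggers = n_triggers, isi_s = isi_s,
             background = list(band = c(20, 1000), rms_mV = rms_mV),
             current_grid = seq(0.5, 3, by = 0.5), ...)
}

scaled_mvc_cfg <- function(n_animals = 4, weeks = c(-1, 1, 2, 3),
                           groups = c("untreated", "chabc_only", "triple"),
                           profiles = default_group_profiles(),
                           n_trials = 1, rms_mV = 0.05) {
  sim_config(fs = 800,
             background = list(band = c(20, 350), rms_mV = rms_mV),
             mvc = list(n_trials = n_trials, trial_s = 0.8, gap_s = 0.2,
                        burst_frac = 0.7, amp_mV = 0.5,
                        grip_mean = 700, grip_cv = 0.12, grip_shared = 0.15),
             artifact = list(move_rate_hz = 0.1, move_amp_mV = 0.3,
                             move_dur_s = 0.3, move_band = c(2, 10),
                             stim_amp_mV = 5, stim_dur_ms = 1),
             group_profiles = profiles, n_animals = n_animals,
             groups = groups, weeks = weeks)
}

scaled_params <- function(...) mep_params(n_select = 8, ...)

# A minimal hand-built mep session: flat signal with chosen events.
flat_mep_session <- function(fs = 2000, events = seq(0.1, by = 0.2,
                                                     length.out = 5),
                             dur_s = NULL, n_channels = 1,
                             value = 0) {
  dur_s <- dur_s %||% (max(events) + 0.2)
  n <- round(dur_s * fs)
  raw_session("s1", "a1", "untreated", -1, "mep", fs,
              matrix(value, n, n_channels),
              channels = paste0("biceps_", c("R", "L"))[seq_len(n_channels)],
              stim_events = events, stim_current_mA = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Mann-Whitney oracle: U from pairwise comparison counts
# (not rank sums), two-tailed p by enumerating y-index subsets.
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) {
      if (ai > bj) u <- u + 1 else if (ai == bj) u <- u + 0.5
    }
    u
  }
  pooled <- c(x, y)
  U_obs <- u_of(x, y)
  mu <- n1 * n2 / 2
  idx <- utils::combn(n1 + n2, n2)   # positions assigned to the y sample
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    yy <- pooled[idx[, j]]
    xx <- pooled[-idx[, j]]
    if (abs(u_of(xx, yy) - mu) >= abs(U_obs - mu) - 1e-12) hits <- hits + 1
  }
  list(U = U_obs, p = hits / ncol(idx))
}

# Greenhouse-Geisser epsilon by the original covariance-moment formula
# (a different route than the orthonormal-contrast eigendecomposition).
gg_epsilon_oracle <- function(Y, groups) {
  k <- ncol(Y)
  Yc <- Y
  for (g in unique(groups)) {
    r <- which(groups == g)
    Yc[r, ] <- sweep(Y[r, , drop = FALSE], 2, colMeans(Y[r, , drop = FALSE]))
  }
  S <- crossprod(Yc) / (nrow(Y) - length(unique(groups)))
  sbar <- mean(diag(S)); mbar <- mean(S)
  row_m <- rowMeans(S)
  (k^2 * (sbar - mbar)^2) /
    ((k - 1) * (sum(S^2) - 2 * k * sum(row_m^2) + k^2 * mbar^2))
}

# Balanced split-plot panel with chosen effects.
make_panel <- function(n_per_group = 4, groups = c("A", "B", "C"),
                       weeks = 1:5, group_eff = 0, week_eff = 0,
                       subj_sd = 1, noise_sd = 1, seed = 1) {
  set.seed(seed)
  an <- paste0("s", seq_len(n_per_group * length(groups)))
  g <- rep(groups, each = n_per_group)
  tab <- expand.grid(animal_id = an, week = weeks,
                     stringsAsFactors = FALSE)
  tab$group <- g[match(tab$animal_id, an)]
  subj <- stats::rnorm(length(an), 0, subj_sd)
  tab$value <- stats::rnorm(nrow(tab), 0, noise_sd) +
    subj[match(tab$animal_id, an)] +
    group_eff * as.numeric(factor(tab$group)) +
    week_eff * tab$week
  tab
}
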