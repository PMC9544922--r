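test_that("baseline estimation matches simple and analytic cases", {
  fs <- 1000
  tr <- emg_trace(rep(0.1, 200), fs = fs, t0_ms = -100)
  expect_equal(estimate_baseline(tr, c(-80, -20)), 0.1)
  expect_equal(estimate_baseline(emg_trace(rep(0, 200), fs, t0_ms = -100),
                                 c(-80, -20)), 0)
  expect_error(estimate_baseline(tr, c(-80, 20)), "pre-stimulus")
  # rectified band-limited Gaussian noise: mean |x| = rms * sqrt(2/pi),
  # preserved through smoothing and low-pass (checked pre DC correction)
  set.seed(21)
  fs <- 5000
  rms <- 0.05
  x <- rnorm(3 * fs)
  x <- x / sqrt(mean(x^2)) * rms
  tr <- lowpass(smooth5(rectify(emg_trace(x, fs, t0_ms = -3000))))
  b <- estimate_baseline(tr, c(-2800, -200))
  expect_lt(abs(b / (rms * sqrt(2 / pi)) - 1), 0.10)
})

test_that("onset/offset detection finds sustained threshold crossings", {
  fs <- 10000
  t_ms <- seq(-50, 100, by = 1000 / fs)
  x <- rep(0.1, length(t_ms))
  x[t_ms >= 10 & t_ms <= 30] <- 0.5
  tr <- emg_trace(x, fs, t0_ms = -50)
  d <- detect_onset_offset(tr, baseline_mV = 0.1)
  expect_true(d$detected)
  expect_lt(abs(d$onset_ms - 10), 1000 / fs + 1e-9)
  expect_lt(abs(d$offset_ms - 30), 1000 / fs + 1e-9)
  # signal never exceeding 1.15 * baseline: no response
  x2 <- rep(0.1, length(t_ms))
  x2[t_ms > 0] <- 0.114
  expect_false(detect_onset_offset(emg_trace(x2, fs, t0_ms = -50), 0.1)$detected)
  # all-zero trace: absolute floor prevents detection at zero baseline
  expect_false(detect_onset_offset(emg_trace(numeric(length(t_ms)), fs,
                                             t0_ms = -50), 0)$detected)
  # runs shorter than min_run_ms do not qualify
  x3 <- rep(0, length(t_ms))
  x3[t_ms >= 20 & t_ms <= 21] <- 1
  expect_false(detect_onset_offset(emg_trace(x3, fs, t0_ms = -50), 0,
                                   min_run_ms = 3)$detected)
  expect_error(detect_onset_offset(tr, 0.1, search_window_ms = c(50, 10)),
               "search window")
})

test_that("AUC is the trapezoidal integral in mV*ms", {
  fs <- 10000
  t_ms <- seq(0, 20, by = 1000 / fs)
  const <- emg_trace(rep(1, length(t_ms)), fs)
  expect_equal(compute_auc(const, 0, 10), 10)
  expect_equal(compute_auc(emg_trace(numeric(length(t_ms)), fs), 0, 10), 0)
  # symmetric triangle peaking at 2 mV over 10 ms: area 10 mV*ms
  tri <- 2 * pmax(0, 1 - abs(t_ms - 5) / 5)
  expect_equal(compute_auc(emg_trace(tri, fs), 0, 10), 10, tolerance = 1e-6)
  expect_error(compute_auc(const, -5, 10), "outside")
  expect_error(compute_auc(const, 12, 10), "onset")
  # linearity: doubling the trace doubles the AUC at fixed bounds
  expect_equal(compute_auc(emg_trace(2 * tri, fs), 0, 10),
               2 * compute_auc(emg_trace(tri, fs), 0, 10))
})

test_that("noiseless synthetic MEPs are recovered to closed form", {
  cfg <- sim_config(fs = 20000, n_triggers = 8, isi_s = 0.3,
                    background = list(band = c(20, 1000), rms_mV = 0),
                    artifact = list(move_rate_hz = 0, move_amp_mV = 0,
                                    move_dur_s = 0.5, move_band = c(2, 10),
                                    stim_amp_mV = 5, stim_dur_ms = 1))
  p <- scaled_params()
  s <- simulate_mep_session(cfg, "a1", "triple", -1, 1.5, seed = 7, params = p)
  r <- analyze_mep_session(s, params = p)
  expect_true(r$detected)
  expect_lt(abs(r$onset_ms - s$truth$true_onset_ms), 1)
  expect_lt(abs(r$offset_ms - s$truth$true_offset_ms), 1)
  expect_lt(abs(r$auc_mVms / s$truth$true_auc_mVms - 1), 0.02)
})

test_that("detection flags and onset are reliable at the default noise level", {
  cfg <- scaled_mep_cfg(n_triggers = 16, isi_s = 0.25)
  p <- mep_params(n_select = 12)
  for (sd in 1:4) {
    s <- simulate_mep_session(cfg, "a1", "triple", -1, 1.5, seed = sd,
                              params = p)
    r <- analyze_mep_session(s, params = p)
    expect_true(r$detected)
    expect_lt(abs(r$onset_ms - s$truth$true_onset_ms), 1)
    sub <- simulate_mep_session(cfg, "a1", "untreated", 1, 0.25, seed = sd,
                                detail_truth = FALSE)
    expect_false(analyze_mep_session(sub, params = p)$detected)
  }
})

test_that("AUC and duration are non-decreasing in burst amplitude", {
  p <- scaled_params()
  amps <- c(0.2, 0.4, 0.8)
  for (sd in 1:3) {
    res <- lapply(amps, function(a) {
      cfg <- scaled_mep_cfg(n_triggers = 10, isi_s = 0.25)
      cfg$mep$amp_mV <- a
      s <- simulate_mep_session(cfg, "a1", "triple", -1, 1.5, seed = sd,
                                params = p, detail_truth = FALSE)
      analyze_mep_session(s, params = p)
    })
    aucs <- vapply(res, function(r) r$auc_mVms, 1)
    durs <- vapply(res, function(r) r$duration_ms, 1)
    expect_true(all(diff(aucs) >= 0))
    expect_true(all(diff(durs) >= -1e-9))
  }
})

test_that("stimulating at 1.5x threshold gives at least the threshold AUC", {
  cfg <- scaled_mep_cfg(n_triggers = 10, isi_s = 0.25)
  p <- scaled_params()
  for (sd in 1:3) {
    s1 <- simulate_mep_session(cfg, "a1", "triple", -1, 1.0, seed = sd,
                               params = p, detail_truth = FALSE)
    s15 <- simulate_mep_session(cfg, "a1", "triple", -1, 1.5, seed = sd,
                                params = p, detail_truth = FALSE)
    expect_gte(analyze_mep_session(s15, params = p)$auc_mVms,
               analyze_mep_session(s1, params = p)$auc_mVms)
  }
})

test_that("threshold search returns the smallest detected current", {
  mk <- function(cur, det) list(current_mA = cur,
                                result = structure(list(detected = det),
                                                   class = "mep_result"))
  grid <- c(0.5, 1, 1.5, 2)
  series <- Map(mk, grid, grid >= 1.5)
  expect_equal(find_threshold(series), 1.5)
  expect_true(is.na(find_threshold(Map(mk, grid, rep(FALSE, 4)))))
  expect_warning(
    thr <- find_threshold(Map(mk, grid, c(FALSE, TRUE, FALSE, TRUE))),
    "non-monotone")
  expect_equal(thr, 1)
  expect_error(find_threshold(Map(mk, c(1, 0.5), c(TRUE, TRUE))), "ascending")
})

test_that("configured thresholds are recovered from recruitment series", {
  # scaled sweep counts keep the full design's structure: acquire 3x the
  # averaged count (24 of which 8 are selected, like 60/20) so dirty
  # sweeps can be deselected, and scale the background RMS by sqrt(8/20)
  # so the averaged residual noise matches the full design
  cfg <- scaled_mep_cfg(n_triggers = 24, isi_s = 0.25,
                        rms_mV = 0.05 * sqrt(8 / 20))
  p <- scaled_params()
  for (thr_true in c(1.0, 1.5, 2.0)) {
    series <- simulate_recruitment_series(cfg, "a1", week = -1, seed = 11,
                                          threshold_mA = thr_true, params = p)
    results <- lapply(series, function(e) {
      list(current_mA = e$current_mA,
           result = analyze_mep_session(e$session, params = p))
    })
    est <- find_threshold(results)
    expect_lte(abs(est - thr_true), 0.5)  # within one grid step
  }
  # truth above the grid maximum: nothing detected
  series <- simulate_recruitment_series(cfg, "a1", week = -1, seed = 11,
                                        threshold_mA = 99, params = p)
  results <- lapply(series, function(e) {
    list(current_mA = e$current_mA,
         result = analyze_mep_session(e$session, params = p))
  })
  expect_true(is.na(find_threshold(results)))
})
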