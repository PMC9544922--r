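test_that("simulation is bit-identical for a fixed seed", {
  cfg <- scaled_mep_cfg(n_triggers = 4)
  s1 <- simulate_mep_session(cfg, "a1", "triple", -1, 1.5, seed = 9,
                             detail_truth = FALSE)
  s2 <- simulate_mep_session(cfg, "a1", "triple", -1, 1.5, seed = 9,
                             detail_truth = FALSE)
  expect_identical(s1$signal, s2$signal)
  s3 <- simulate_mep_session(cfg, "a1", "triple", -1, 1.5, seed = 10,
                             detail_truth = FALSE)
  expect_false(identical(s1$signal, s3$signal))
  cfgm <- scaled_mvc_cfg()
  m1 <- simulate_mvc_session(cfgm, "a1", "triple", -1, seed = 9)
  m2 <- simulate_mvc_session(cfgm, "a1", "triple", -1, seed = 9)
  expect_identical(m1$signal, m2$signal)
  expect_identical(m1$trial_events, m2$trial_events)
  c1 <- simulate_mn_counts(c(C2 = 0, C3 = 0, C4 = 23, C5 = 146, C6 = 167,
                             C7 = 249, C8 = 160, T1 = 19, T2 = 0),
                           n_animals = 5, seed = 2)
  c2 <- simulate_mn_counts(c(C2 = 0, C3 = 0, C4 = 23, C5 = 146, C6 = 167,
                             C7 = 249, C8 = 160, T1 = 19, T2 = 0),
                           n_animals = 5, seed = 2)
  expect_identical(c1, c2)
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_mep_session(scaled_mep_cfg(n_triggers = 3),
                                 "a1", "triple", -1, 1.5, seed = 1,
                                 detail_truth = FALSE))
  expect_identical(.Random.seed, before)
})

test_that("a zero amplitude multiplier yields a null session", {
  prof <- default_group_profiles()
  prof$triple[] <- 0
  cfg <- scaled_mep_cfg(n_triggers = 10, isi_s = 0.25,
                        group_profiles = prof)
  cfg$artifact$move_rate_hz <- 0
  s <- simulate_mep_session(cfg, "a1", "triple", 5, 1.5, seed = 3,
                            detail_truth = FALSE)
  expect_identical(s$truth$amp_eff, 0)
  # pre- and post-stimulus RMS distributions agree (no stimulus-locked power)
  sw <- epoch_sweeps(s)
  t_ms <- sw$t0_ms + (seq_len(ncol(sw$sweeps)) - 1) / sw$fs * 1000
  pre_rms <- sqrt(rowMeans(sw$sweeps[, t_ms < -3]^2))
  post_rms <- sqrt(rowMeans(sw$sweeps[, t_ms > 3 & t_ms < 50]^2))
  expect_lt(abs(mean(post_rms) / mean(pre_rms) - 1), 0.1)
  # and the average is scored as no response
  p <- scaled_params()
  expect_false(analyze_mep_session(s, params = p)$detected)
})

test_that("subthreshold stimulation evokes no burst", {
  cfg <- scaled_mep_cfg(n_triggers = 10, isi_s = 0.25)
  s <- simulate_mep_session(cfg, "a1", "triple", -1, current_mA = 0.5,
                            seed = 6, threshold_mA = 1.0)
  expect_identical(s$truth$amp_eff, 0)
  expect_false(analyze_mep_session(s, params = scaled_params())$detected)
  expect_error(simulate_mep_session(cfg, "a1", "triple", 99, 1.5, seed = 1),
               "not in cfg")
})

test_that("MVC bursts scale as the closed-form expectation predicts", {
  p <- mep_params()
  cfg1 <- scaled_mvc_cfg(n_trials = 3)
  cfg2 <- scaled_mvc_cfg(n_trials = 3)
  cfg2$mvc$amp_mV <- 2 * cfg1$mvc$amp_mV
  s1 <- simulate_mvc_session(cfg1, "a1", "triple", -1, seed = 8)
  s2 <- simulate_mvc_session(cfg2, "a1", "triple", -1, seed = 8)
  # measured MVC tracks the closed-form expected AUC at both amplitudes
  expect_lt(abs(quantify_mvc(s1, p)$mvc_mVms /
                  s1$truth$expected_mvc_auc_mVms - 1), 0.1)
  expect_lt(abs(quantify_mvc(s2, p)$mvc_mVms /
                  s2$truth$expected_mvc_auc_mVms - 1), 0.1)
  # doubling the burst amplitude doubles the expected AUC above background
  rho <- mepkit:::lowpass_var_ratio(cfg1$fs, cfg1$background$band,
                                    p$lowpass_hz)
  bg_auc <- sqrt(2 / pi) * sqrt(rho) * cfg1$background$rms_mV *
    cfg1$mvc$trial_s * 1000
  r <- (s2$truth$expected_mvc_auc_mVms - bg_auc) /
    (s1$truth$expected_mvc_auc_mVms - bg_auc)
  expect_lt(abs(r - 2), 0.15)
  # zero multiplier: trial AUC is background-only
  prof <- default_group_profiles()
  prof$triple[] <- 0
  cfg0 <- scaled_mvc_cfg(n_trials = 3, profiles = prof)
  cfg0$artifact$move_rate_hz <- 0
  s0 <- simulate_mvc_session(cfg0, "a1", "triple", 2, seed = 8)
  expect_lt(abs(quantify_mvc(s0, p)$mvc_mVms / bg_auc - 1), 0.1)
})

test_that("recruitment series bracket the configured threshold", {
  cfg <- scaled_mep_cfg(n_triggers = 6, isi_s = 0.25)
  series <- simulate_recruitment_series(cfg, "a1", week = -1, seed = 2,
                                        threshold_mA = 1.5,
                                        current_grid = c(0.5, 1, 1.5, 2))
  expect_identical(vapply(series, `[[`, 1, "current_mA"), c(0.5, 1, 1.5, 2))
  amps <- vapply(series, function(e) e$session$truth$amp_eff, 1)
  expect_true(all(amps[1:2] == 0))
  expect_true(all(amps[3:4] > 0))
  expect_error(simulate_recruitment_series(cfg, "a1", seed = 2,
                                           current_grid = numeric()),
               "empty")
  # determinism of the whole series
  s2 <- simulate_recruitment_series(cfg, "a1", week = -1, seed = 2,
                                    threshold_mA = 1.5,
                                    current_grid = c(0.5, 1, 1.5, 2))
  expect_identical(series[[2]]$session$signal, s2[[2]]$session$signal)
})

test_that("cohorts are full factorials with a complete truth table", {
  cfg <- scaled_mvc_cfg(n_animals = 2, weeks = c(-1, 1, 2))
  co <- simulate_cohort(cfg, seed = 4, modalities = "mvc")
  expect_length(co$sessions, 3 * 2 * 3)   # groups x animals x weeks
  expect_identical(nrow(co$truth), 18L)
  expect_true(all(table(co$truth$group, co$truth$week) == 2))
  expect_false(any(is.na(co$truth$expected_mvc_auc_mVms)))
  # per-animal thresholds are stable across weeks
  thr <- tapply(co$truth$threshold_mA, co$truth$animal_id,
                function(v) length(unique(v)))
  expect_true(all(thr == 1))
  # bundle-directory mode round-trips
  dir <- withr::local_tempdir()
  co2 <- simulate_cohort(cfg, seed = 4, modalities = "mvc", dir = dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- read_session(co2$sessions[[1]])
  expect_identical(validate_session(back), character())
  expect_lt(max(abs(back$signal - co$sessions[[1]]$signal)), 1e-9)
})

test_that("simulated motor-neuron counts honour their level means", {
  means0 <- setNames(rep(0, 9),
                     c("C2", "C3", "C4", "C5", "C6", "C7", "C8", "T1", "T2"))
  z <- simulate_mn_counts(means0, n_animals = 4, seed = 1)
  expect_true(all(z$count == 0L))
  expect_identical(validate_mn_counts(z), character())
  # law of large numbers against the packaged naive level means
  tab <- load_mn_counts()
  naive_means <- with(summarize_counts(tab),
                      setNames(mean[group == "naive" & level != "Total"],
                               level[group == "naive" & level != "Total"]))
  sim <- simulate_mn_counts(naive_means, n_animals = 200, dispersion = 5,
                            seed = 42)
  sm <- tapply(sim$count, sim$level, mean)
  for (lv in names(naive_means)) {
    mu <- naive_means[[lv]]
    if (mu == 0) {
      expect_equal(unname(sm[lv]), 0)
    } else {
      se <- sqrt(mu + mu^2 / 5) / sqrt(200)
      expect_lt(abs(sm[lv] - mu), 3 * se)
    }
  }
  expect_error(simulate_mn_counts(replace(naive_means, 1, -1), 5), ">= 0")
})
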