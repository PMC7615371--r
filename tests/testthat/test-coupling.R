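test_that("RS intervals follow the 4-preceding / 4-following convention", {
  b <- beat_series(0:9)
  rs <- rs_intervals(b, 4.45)
  expect_equal(unname(rs[1, "RS_m1"]), 0.45)
  expect_equal(unname(rs[1, "RS_p1"]), 0.55)
  expect_equal(unname(rs[1, c("RS_m4", "RS_m3", "RS_m2")]),
               c(3.45, 2.45, 1.45))
  expect_equal(unname(rs[1, "RS_p4"]), 3.55)
  # boundary: a wave exactly on a beat assigns that beat as preceding
  rs0 <- rs_intervals(b, 4)
  expect_equal(unname(rs0[1, "RS_m1"]), 0)
  expect_equal(unname(rs0[1, "RS_p1"]), 1)
  # waves without 4 beats on each side are skipped
  expect_message(rs_skip <- rs_intervals(b, c(1.5, 4.5)), "skipped")
  expect_equal(nrow(rs_skip), 1L)
  expect_equal(attr(rs_skip, "n_skipped"), 1L)
})

test_that("fully coupled, jitter-free recordings give RS_m1 == lag", {
  cfg <- volunteer_sim_config(phase_scale = 0.25, sw_coupling_prob = 1,
                              rsa_amp_base = 0, rsa_amp_slope = 0,
                              lf_amp = 0, seed = 17)
  rec <- simulate_volunteer(cfg, events_only = TRUE)
  b <- beat_series(rec$truth_beats, rec$truth_rwa)
  rs <- rs_intervals(b, rec$truth_sw$onset)
  expect_equal(unname(rs[, "RS_m1"]),
               rep(cfg$sw_coupling_lag, nrow(rs)), tolerance = 1e-12)
})

test_that("proportional entropy reproduces its closed-form identities", {
  # all values in one bin: perfect coupling
  expect_equal(as.numeric(proportional_entropy(rep(0.42, 40), 0, 1)), 0)
  # exactly uniform bin counts: maximum entropy
  u <- rep(seq(0.05, 0.95, by = 0.1), each = 4)
  expect_equal(as.numeric(proportional_entropy(u, 0, 1)), 1)
  # 30/10 split across two bins, hand-evaluated
  v <- c(rep(0.05, 30), rep(0.15, 10))
  expect_equal(as.numeric(proportional_entropy(v, 0, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(10),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(proportional_entropy(v, 0, 1)), 4), 0.2442)
  # out-of-range values are excluded, not clipped
  e <- proportional_entropy(c(rep(0.5, 10), 2, 3), 0, 1)
  expect_equal(as.numeric(e), 0)
  expect_equal(attr(e, "n_excluded"), 2L)
  expect_true(is.na(proportional_entropy(c(5, 6), 0, 1)))
})

test_that("entropy is invariant to affine rescaling and matches the oracle", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    v <- runif(n)
    ref <- proportional_entropy(v, 0, 1)
    expect_equal(as.numeric(ref), entropy_oracle(v, 0, 1),
                 tolerance = 1e-12)
    a <- runif(1, 0.1, 5); c0 <- runif(1, -3, 3)
    expect_equal(as.numeric(proportional_entropy(a * v + c0, c0, a + c0)),
                 as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("windowed entropy separates coupled from uncoupled cohorts", {
  # kappa = 1 without jitter: every window is a single bin
  cfg1 <- volunteer_sim_config(sw_coupling_prob = 1, rsa_amp_base = 0,
                               rsa_amp_slope = 0, lf_amp = 0, seed = 18)
  r1 <- simulate_volunteer(cfg1, events_only = TRUE)
  b1 <- beat_series(r1$truth_beats)
  e1 <- windowed_entropy(rs_intervals(b1, r1$truth_sw$onset), b1)
  expect_equal(e1$subject_mean_shp, 0)

  # kappa = 0: near-maximal entropy with the 40-sample plug-in bias
  cfg0 <- volunteer_sim_config(sw_coupling_prob = 0, seed = 18)
  r0 <- simulate_volunteer(cfg0, events_only = TRUE)
  b0 <- beat_series(r0$truth_beats)
  e0 <- windowed_entropy(rs_intervals(b0, r0$truth_sw$onset), b0)
  bias <- 9 / (2 * 40 * log(10))
  expect_lt(abs(e0$subject_mean_shp - (1 - bias)), 0.03)

  # kappa = 1 with physiological RR jitter still sits far below kappa = 0
  cfgj <- volunteer_sim_config(sw_coupling_prob = 1, seed = 18)
  rj <- simulate_volunteer(cfgj, events_only = TRUE)
  bj <- beat_series(rj$truth_beats)
  ej <- windowed_entropy(rs_intervals(bj, rj$truth_sw$onset), bj)
  expect_lt(ej$subject_mean_shp, e0$subject_mean_shp)

  # per-window probabilities sum to one; entropies stay in [0, 1]
  expect_true(all(abs(rowSums(e0$P) - 1) < 1e-9))
  expect_true(all(e0$windows$shp >= 0 & e0$windows$shp <= 1))

  # fewer waves than one window yields a logged missing value
  few <- rs_intervals(b0, r0$truth_sw$onset[1:10])
  expect_message(ef <- windowed_entropy(few, b0), "waves")
  expect_true(is.na(ef$subject_mean_shp))
})

test_that("subject entropy is non-increasing in coupling probability", {
  kappas <- c(0, 0.25, 0.5, 0.75, 1)
  means <- matrix(NA_real_, 20, length(kappas))
  for (s in 1:20) {
    for (j in seq_along(kappas)) {
      cfg <- volunteer_sim_config(sw_coupling_prob = kappas[j],
                                  seed = 100 + s)
      r <- simulate_volunteer(cfg, events_only = TRUE)
      b <- beat_series(r$truth_beats)
      means[s, j] <- windowed_entropy(rs_intervals(b, r$truth_sw$onset),
                                      b)$subject_mean_shp
    }
  }
  avg <- colMeans(means)
  expect_true(all(diff(avg) <= 0))
})

test_that("surrogate calibration reproduces the published threshold", {
  sur <- surrogate_threshold(seed = 7)
  expect_lt(abs(sur$threshold - 0.970), 0.003)
  chi2 <- 1 - qchisq(0.999, df = 9) / (2 * 200 * log(10))
  expect_lt(abs(sur$threshold - chi2), 0.003)
  # deterministic given the seed
  expect_identical(sur$threshold, surrogate_threshold(seed = 7)$threshold)
  expect_false(identical(sur$threshold,
                         surrogate_threshold(seed = 8)$threshold))
  # a degenerate all-identical series has zero entropy
  expect_equal(as.numeric(proportional_entropy(rep(0.3, 200), 0, 1)), 0)
  expect_error(surrogate_threshold(n_surrogates = 500), ">= 1000")
})

test_that("bias-matched surrogates sit below the single-histogram null", {
  sw <- surrogate_threshold(n_surrogates = 1000, seed = 7,
                            mode = "windowed")
  sh <- surrogate_threshold(n_surrogates = 1000, seed = 7)
  # windowed-mean nulls concentrate near the 40-sample bias (~0.95)
  expect_lt(mean(sw$shp), mean(sh$shp))
  expect_lt(abs(mean(sw$shp) - (1 - 9 / (2 * 40 * log(10)))), 0.02)
  expect_lt(sw$threshold, sh$threshold)
})

test_that("time-locked averaging recovers the configured coupling lag", {
  cfg <- volunteer_sim_config(phase_scale = 0.25, sw_coupling_prob = 1,
                              seed = 19)
  rec <- simulate_volunteer(cfg)
  eeg <- preprocess_eeg(rec$eeg)
  waves <- detect_slow_waves(eeg)
  tla <- time_locked_average(rec$ecg, eeg, waves)
  expect_lt(abs(-tla$peak_lag - cfg$sw_coupling_lag), 0.03)
  # the EEG average shows the canonical shape: downward crossing at lag 0
  i0 <- which.min(abs(tla$lag_eeg))
  expect_lt(abs(tla$eeg_mean[i0]), 12)
  expect_lt(tla$eeg_mean[i0 + 25], -30) # deep negative phase 0.25 s in
  expect_gt(tla$eeg_mean[i0 - 25], 5)   # positive run-up before onset
  # uncoupled waves average incoherently toward zero
  cfg0 <- volunteer_sim_config(phase_scale = 0.25, sw_coupling_prob = 0,
                               seed = 19)
  rec0 <- simulate_volunteer(cfg0)
  eeg0 <- preprocess_eeg(rec0$eeg)
  tla0 <- time_locked_average(rec0$ecg, eeg0, detect_slow_waves(eeg0))
  sel <- tla$lag_ecg >= -1 & tla$lag_ecg < 0
  expect_gt(max(tla$ecg_band_mean[sel]), 3 * max(tla0$ecg_band_mean[sel]))
  expect_error(time_locked_average(rec$ecg, eeg, waves$onset[1:5]),
               ">= 10")
})
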