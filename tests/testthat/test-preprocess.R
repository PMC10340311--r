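test_that("detect_r_peaks finds planted beats accurately", {
  dur <- 60
  beats <- seq(0.5, dur - 0.5, by = 1)              # 60 bpm
  ecg <- render_ecg(beats, NULL, params = list(duration_s = dur, noise_sd = 0))
  det <- detect_r_peaks(ecg)
  expect_true(abs(length(det$times) - 60) <= 1)
  err <- vapply(det$times, function(t) min(abs(t - beats)), 0.0)
  expect_lte(stats::median(err), 0.020)
  # flat signal -> no beats, not an error
  expect_length(detect_r_peaks(sampled_signal(rep(0, 256 * 15), 256))$times, 0)
  expect_error(detect_r_peaks(sampled_signal(rnorm(256), 256)), "10 s")
})

test_that("detected beats match the generator's beat times on a full record", {
  rec <- quick_subject(seed = 31, duration_s = 900)
  det <- detect_r_peaks(rec$ecg)
  err <- vapply(det$times, function(t) min(abs(t - rec$beat_times)), 0.0)
  expect_lte(stats::median(err), 0.020)
})

test_that("reject_ectopic flags rate jumps but tolerates drift", {
  expect_error(reject_ectopic(beat_series(c(0, 1))), "at least 3")
  # constant rhythm: nothing flagged
  b <- reject_ectopic(beat_series(0:20))
  expect_true(all(b$valid))
  # one 0.4 s interval inside a 1.0 s rhythm: its beat flagged
  tb <- c(0:10, 10.4, 11:20 + 0.4)
  fl <- reject_ectopic(beat_series(tb))
  expect_identical(which(!fl$valid), 12L)
  expect_identical(fl$times, tb)                   # times unchanged
  # gradual 5%/beat drift stays below the 30% limit
  td <- cumsum(1.0 * 1.05^(0:20))
  expect_true(all(reject_ectopic(beat_series(td))$valid))
})

test_that("rr_series interpolates valid intervals and zeroes artifact spans", {
  b <- beat_series(seq(0.5, 59.5, by = 1))
  rr <- rr_series(b, duration_s = 60)
  expect_length(rr$values, 240)                    # ceil(60 * 4)
  expect_true(all(abs(rr$values - 1) < 1e-9))
  # flagged beat -> contiguous zeros over its enclosing inter-beat span
  v <- rep(TRUE, 60); v[30] <- FALSE
  rrz <- rr_series(beat_series(seq(0.5, 59.5, by = 1), v), duration_s = 60)
  z <- which(rrz$values == 0)
  expect_true(length(z) > 0)
  t_z <- (z - 1) / 4
  expect_true(all(t_z >= 28.5 & t_z <= 30.5))      # span [t29, t31]
  expect_true(all(diff(z) == 1))
  expect_error(rr_series(beat_series(c(1, 2), c(TRUE, FALSE))), "2 valid")
})

test_that("extract_edr recovers the planted respiratory frequency", {
  dur <- 300
  t32 <- seq(1 / 32, dur, by = 1 / 32)
  resp <- sampled_signal(sin(2 * pi * 0.25 * t32), 32)
  beats <- generate_beat_times(dur, list(base_bpm = 62, jitter_sd = 0.005),
                               seed = 7)
  ecg <- render_ecg(beats, resp, params = list(duration_s = dur, mod_depth = 0.2))
  bs <- detect_r_peaks(ecg)
  edr <- extract_edr(ecg, bs, params = list(fs = 4), duration_s = dur)
  expect_equal(edr$fs, 4)
  expect_length(edr$values, 1200)
  expect_equal(spectral_peak(edr$values, 4, c(0.1, 0.5)), 0.25,
               tolerance = 0.02)
  # depth-0 ECG: EDR variance collapses
  ecg0 <- render_ecg(beats, resp, params = list(duration_s = dur, mod_depth = 0,
                                                noise_sd = 0.01))
  edr0 <- extract_edr(ecg0, detect_r_peaks(ecg0), params = list(fs = 4),
                      duration_s = dur)
  expect_lt(stats::var(edr0$values), 0.05 * stats::var(edr$values))
})

test_that("preprocess_effort removes DC and keeps the respiration band", {
  t32 <- seq(1 / 32, 300, by = 1 / 32)
  # constant input -> ~0 after high-pass
  flat <- preprocess_effort(sampled_signal(rep(3, length(t32)), 32))
  expect_lt(max(abs(flat$values)), 1e-6)
  # 0.25 Hz unit sinusoid passes within 5%
  s <- preprocess_effort(sampled_signal(sin(2 * pi * 0.25 * t32), 32))
  expect_lt(abs(max(abs(s$values[200:1000])) - 1), 0.05)
})

test_that("the three model inputs share rate and length over a record", {
  rec <- quick_subject(seed = 41, duration_s = 900)
  prep <- preprocess_record(rec)
  expect_equal(prep$rr$fs, 4)
  expect_equal(prep$edr$fs, 4)
  expect_equal(prep$re$fs, 4)
  expect_equal(length(prep$rr$values), length(prep$edr$values))
  expect_equal(length(prep$rr$values), length(prep$re$values))
})

test_that("RR series reproduces planted intervals on clean input", {
  dur <- 300
  beats <- generate_beat_times(dur, list(base_bpm = 70, jitter_sd = 0,
                                         drift_bpm = 2, rsa_bpm = 1,
                                         excursion_bpm = 0), seed = 8)
  ecg <- render_ecg(beats, NULL, params = list(duration_s = dur, noise_sd = 0.01))
  det <- reject_ectopic(detect_r_peaks(ecg))
  rr <- rr_series(det, duration_s = dur)
  rr_true <- stats::approx((beats[-1] + beats[-length(beats)]) / 2, diff(beats),
                           xout = signal_times(rr), rule = 2)$y
  core <- 40:(length(rr_true) - 40)
  expect_lt(max(abs(rr$values[core] - rr_true[core])), 0.025)
})
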