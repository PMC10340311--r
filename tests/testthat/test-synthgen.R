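test_that("event_list enforces ordering, overlap and duration invariants", {
  expect_equal(nrow(event_list()), 0L)
  ev <- event_list(c(50, 10), c(70, 25), c("central", "hypopnea"))
  expect_equal(ev$start_s, c(10, 50))          # sorted on construction
  expect_error(event_list(0, 0, "central"), "start_s < end_s")
  expect_error(event_list(c(0, 5), c(10, 15), "central"), "overlap")
  expect_error(event_list(0, 5, "central", min_duration = 10), "shorter")
  expect_error(event_list(0, 20, "apnoea"), "unknown event type")
})

test_that("plant_events hits the target count and respects the sleep mask", {
  expect_equal(nrow(plant_events(3600, 0, seed = 1)), 0L)
  # 8 h all-sleep, AHI 18 -> 144 events
  ev <- plant_events(28800, 18, sleep_mask = rep(TRUE, 28800), seed = 2)
  expect_equal(nrow(ev), 144)
  expect_true(all(ev$end_s - ev$start_s >= 10))
  gaps <- ev$start_s[-1] - ev$end_s[-nrow(ev)]
  expect_true(all(gaps >= 5))
  # degenerate mix
  ev2 <- plant_events(7200, 10, mix = c(1, 0, 0, 0), seed = 3)
  expect_true(all(ev2$type == "hypopnea"))
  # events only during sleep
  mask <- rep(c(FALSE, TRUE), c(1800, 5400))
  ev3 <- plant_events(7200, 20, sleep_mask = mask, seed = 4)
  expect_true(all(ev3$start_s >= 1800))
  # infeasible density errors
  expect_error(plant_events(3600, 400, sleep_mask = rep(TRUE, 3600), seed = 5),
               "infeasible")
})

test_that("generate_hypnogram produces a plausible, reproducible stage sequence", {
  h <- generate_hypnogram(600, seed = 1)
  expect_length(h$stages, 20)                   # 600 / 30
  expect_identical(h$stages, generate_hypnogram(600, seed = 1)$stages)
  # forcing all-wake leaves zero sleep time, unusable for AHI
  hw <- generate_hypnogram(600, stage_params = list(latency_epochs = 99L), seed = 1)
  expect_equal(total_sleep_time(hw), 0)
  expect_error(compute_ahi(event_list(), hw), "zero total sleep time")
  h2 <- generate_hypnogram(14400, seed = 2)
  expect_gt(total_sleep_time(h2), 0)
  expect_equal(h2$stages[1], "W")               # wake at the edge
})

test_that("generate_position_track labels every second", {
  p <- generate_position_track(120, seed = 1)
  expect_length(p$labels, 120)
  pc <- generate_position_track(300, params = list(categories = "supine",
                                                   probs = 1), seed = 1)
  expect_true(all(pc$labels == "supine"))
  expect_identical(generate_position_track(500, seed = 9)$labels,
                   generate_position_track(500, seed = 9)$labels)
})

test_that("beat times carry event-linked heart-rate excursions", {
  b <- generate_beat_times(120, list(base_bpm = 60, jitter_sd = 0,
                                     drift_bpm = 0, rsa_bpm = 0,
                                     excursion_bpm = 0), seed = 1)
  expect_equal(diff(b), rep(1, length(b) - 1), tolerance = 1e-9)
  ev <- event_list(c(100, 300), c(130, 335), c("obstructive", "central"))
  b2 <- generate_beat_times(600, list(excursion_bpm = 10), ev, seed = 2)
  expect_true(all(diff(b2) > 0))
  rr <- diff(b2); mid <- (b2[-1] + b2[-length(b2)]) / 2
  inside <- (mid >= 100 & mid < 140) | (mid >= 300 & mid < 345)
  expect_gt(diff(range(rr[inside])), diff(range(rr[!inside & mid > 30])))
  # ectopic rate 0 -> no short intervals
  expect_gt(min(diff(b2)), 0.5)
})

test_that("rendered ECG carries respiration in its QRS amplitudes", {
  dur <- 300
  t32 <- seq(1 / 32, dur, by = 1 / 32)
  resp <- sampled_signal(sin(2 * pi * 0.25 * t32), 32)
  beats <- generate_beat_times(dur, list(base_bpm = 66, jitter_sd = 0.005),
                               seed = 3)
  expect_error(render_ecg(numeric(0)), "empty beat list")
  ecg <- render_ecg(beats, resp, params = list(duration_s = dur,
                                               mod_depth = 0.2,
                                               noise_sd = 0.01,
                                               wander_amp = 0))
  # one local maximum above threshold per beat
  v <- ecg$values
  loc <- which(v > 0.5 & v >= c(v[-1], 0) & v > c(0, v[-length(v)]))
  expect_equal(length(loc), length(beats))
  # per-beat peak amplitudes have their spectral peak at the planted rate
  amps <- v[loc]
  bt <- (loc - 1) / ecg$fs
  a4 <- stats::approx(bt, amps, xout = seq(0.25, dur, by = 0.25), rule = 2)$y
  expect_equal(spectral_peak(a4, 4, c(0.1, 0.5)), 0.25, tolerance = 0.02)
  # modulation depth 0 -> amplitudes equal up to noise
  ecg0 <- render_ecg(beats, resp, params = list(duration_s = dur, mod_depth = 0,
                                                noise_sd = 0, wander_amp = 0))
  v0 <- ecg0$values
  loc0 <- which(v0 > 0.5 & v0 >= c(v0[-1], 0) & v0 > c(0, v0[-length(v0)]))
  expect_lt(stats::sd(v0[loc0]) / mean(v0[loc0]), 0.02)
})

test_that("respiratory effort encodes per-type event semantics", {
  dur <- 600
  ev <- event_list(c(100, 300), c(120, 330), c("central", "hypopnea"))
  eff <- generate_respiratory_effort(dur, ev, seed = 2)
  tt <- signal_times(eff)
  rms <- function(lo, hi) sqrt(mean(eff$values[tt >= lo & tt < hi]^2))
  out_mask <- tt < 90 | (tt > 160 & tt < 290) | tt > 370
  rms_out <- sqrt(mean(eff$values[out_mask]^2))
  expect_lt(rms(100, 120), 0.2 * rms_out)       # central: effort nearly absent
  expect_gt(rms(300, 330), 0.3 * rms_out)       # hypopnea: partial reduction
  expect_lt(rms(300, 330), 0.7 * rms_out)
  # no events -> near-constant envelope
  eff0 <- generate_respiratory_effort(dur, event_list(), seed = 3)
  t0 <- signal_times(eff0)
  r1 <- sqrt(mean(eff0$values[t0 < 300]^2))
  r2 <- sqrt(mean(eff0$values[t0 >= 300]^2))
  expect_lt(abs(r1 - r2) / r1, 0.2)
})

test_that("generate_subject is reproducible and internally consistent", {
  r1 <- quick_subject(seed = 21)
  r2 <- quick_subject(seed = 21)
  expect_identical(r1$ecg$values, r2$ecg$values)
  expect_identical(r1$events, r2$events)
  expect_true(validate_subject_record(r1))
  sev <- generate_subject(sim_config(duration_s = 1800), seed = 5,
                          severity = "severe")
  expect_gt(sev$reference_ahi, 30)
})

test_that("record invariant audit passes across random configurations", {
  for (seed in 1:8) {
    rec <- generate_subject(sim_config(duration_s = 1500), seed = seed)
    expect_true(validate_subject_record(rec))
  }
})

test_that("generate_cohort honors class counts, unique ids and seeds", {
  cfg <- sim_config(duration_s = 1200)
  co <- generate_cohort(8, c(normal = 2, mild = 2, moderate = 2, severe = 2),
                        seed = 1, config = cfg)
  expect_length(co, 8)
  expect_equal(sum(vapply(co, `[[`, "", "severity") == "mild"), 2)
  expect_false(anyDuplicated(vapply(co, `[[`, "", "id")) > 0)
  co2 <- generate_cohort(8, c(normal = 2, mild = 2, moderate = 2, severe = 2),
                         seed = 2, config = cfg)
  expect_false(identical(co[[1]]$ecg$values, co2[[1]]$ecg$values))
})
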