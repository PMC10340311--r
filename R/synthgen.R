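#' Simulation configuration for synthetic nights
#'
#' Defaults describe a plausible clinical PSG night: 8-h recording, ECG at
#' 256 Hz, effort belt at 32 Hz, events dominated by hypopneas with smaller
#' obstructive/central/mixed fractions, log-normal event durations clipped to
#' 10-120 s, per-type effort-amplitude depths (central effort nearly absent,
#' obstructive continued but reduced, hypopnea partial), cyclic heart-rate
#' excursions tied to events, and demographics drawn uniformly over adult
#' clinical ranges.
#'
#' @param n_subjects number of subjects when used for a cohort.
#' @param duration_s recording duration in seconds.
#' @param severity_ranges per-class target-AHI ranges (events/h), chosen well
#'   inside the canonical 5/15/30 class bands.
#' @param event_mix fractions over `hypopnea, obstructive, central, mixed`
#'   (must sum to 1).
#' @param dur_meanlog,dur_sdlog log-normal event-duration parameters (s).
#' @param dur_range clip range for event durations in seconds.
#' @param min_gap_s minimum gap between planted events (s).
#' @param base_hr_range baseline heart-rate range (bpm).
#' @param hr_excursion_bpm depth of the bradycardia-tachycardia excursion
#'   accompanying each event (bpm).
#' @param resp_rate_hz respiratory rate in Hz.
#' @param effort_depths per-type multiplicative effort amplitude inside
#'   events; mixed events render a central-depth first half then an
#'   obstructive-depth second half.
#' @param ecg_fs,effort_fs sampling rates in Hz.
#' @param qrs_mod_depth fractional QRS amplitude modulation by respiration
#'   (the EDR substrate).
#' @param noise_sd additive white-noise SD for both rendered signals.
#' @param ectopic_per_h rate of inserted premature (ectopic) beats.
#' @param age_range,bmi_range demographic sampling ranges.
#' @param seed root random seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20,
                       duration_s = 28800,
                       severity_ranges = list(normal = c(0.5, 4),
                                              mild = c(6, 14),
                                              moderate = c(16, 29),
                                              severe = c(31, 55)),
                       event_mix = c(hypopnea = 0.83, obstructive = 0.09,
                                     central = 0.05, mixed = 0.03),
                       dur_meanlog = log(22), dur_sdlog = 0.4,
                       dur_range = c(10, 120),
                       min_gap_s = 5,
                       base_hr_range = c(55, 75),
                       hr_excursion_bpm = 10,
                       resp_rate_hz = 0.25,
                       effort_depths = c(hypopnea = 0.5, obstructive = 0.4,
                                         central = 0.05, mixed = NA),
                       ecg_fs = 256, effort_fs = 32,
                       qrs_mod_depth = 0.2,
                       noise_sd = 0.02,
                       ectopic_per_h = 3,
                       age_range = c(18, 86),
                       bmi_range = c(18.6, 45.2),
                       seed = 1L) {
  stopifnot(duration_s > 0, abs(sum(event_mix) - 1) < 1e-8,
            all(event_mix >= 0), min_gap_s >= 0,
            resp_rate_hz >= 0.1, resp_rate_hz <= 0.5,
            base_hr_range[1] >= 30, base_hr_range[2] <= 180)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Plant SDB events at a target AHI within sleep
#'
#' Inverts the AHI definition (events per hour of sleep) to place a known
#' number of non-overlapping events, entirely inside contiguous sleep runs,
#' with at least `min_gap_s` between events. The event count is
#' `round(target_ahi * TST_h)`, so the realized annotation AHI matches the
#' target up to rounding.
#'
#' @param duration_s recording duration (s).
#' @param target_ahi target events per hour of sleep.
#' @param mix type fractions over [SDB_TYPES] (sum 1).
#' @param dur_params list with `meanlog`, `sdlog`, `range` for log-normal
#'   durations clipped to `range`.
#' @param sleep_mask logical per-second sleep indicator of length
#'   `duration_s`.
#' @param min_gap_s minimum inter-event gap (s).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return an `event_list`.
#' @export
plant_events <- function(duration_s, target_ahi, mix = c(0.83, 0.09, 0.05, 0.03),
                         dur_params = list(meanlog = log(22), sdlog = 0.4,
                                           range = c(10, 120)),
                         sleep_mask = rep(TRUE, duration_s),
                         min_gap_s = 5, seed = NULL) {
  stopifnot(duration_s > 0, target_ahi >= 0)
  if (!is.null(seed)) set.seed(seed)
  tst_s <- sum(sleep_mask)
  n <- round(target_ahi * tst_s / 3600)
  if (n == 0L) return(event_list())

  dur <- stats::rlnorm(n, dur_params$meanlog, dur_params$sdlog)
  dur <- pmin(pmax(dur, dur_params$range[1]), dur_params$range[2])
  if (sum(dur) + n * min_gap_s > 0.9 * tst_s) {
    stop("plant_events: infeasible event density for available sleep time")
  }

  # contiguous sleep runs (start inclusive, end exclusive, in seconds)
  r <- rle(as.logical(sleep_mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start > min(dur) + 2 * min_gap_s, , drop = FALSE]
  if (nrow(runs) == 0L) stop("plant_events: no sleep run can hold an event")

  # first-fit assignment of events to runs, keeping headroom for gaps
  ord <- sample.int(n)
  assign_run <- integer(n)
  load <- rep(0, nrow(runs))          # duration + gap budget already committed
  cap <- runs$end - runs$start
  for (i in ord) {
    need <- dur[i] + min_gap_s
    fit <- which(load + need <= 0.95 * cap)
    if (length(fit) == 0L) fit <- which(load + need + min_gap_s <= cap)
    if (length(fit) == 0L) stop("plant_events: infeasible event density (fragmented sleep)")
    j <- fit[which.max((cap - load)[fit])]
    assign_run[i] <- j
    load[j] <- load[j] + need
  }

  # within each run, spread the free slack over the gaps (Dirichlet weights)
  out_start <- numeric(n); out_end <- numeric(n); k <- 0L
  for (j in seq_len(nrow(runs))) {
    idx <- which(assign_run == j)
    if (length(idx) == 0L) next
    idx <- idx[order(sample.int(length(idx)))]
    m <- length(idx)
    slack <- (cap[j] - sum(dur[idx]) - (m + 1) * min_gap_s)
    w <- stats::rexp(m + 1)
    gaps <- min_gap_s + pmax(slack, 0) * w / sum(w)
    pos <- runs$start[j]
    for (q in seq_len(m)) {
      pos <- pos + gaps[q]
      k <- k + 1L
      out_start[k] <- pos
      out_end[k] <- pos + dur[idx[q]]
      pos <- out_end[k]
    }
  }
  types <- sample(SDB_TYPES, n, replace = TRUE, prob = mix)
  event_list(out_start[seq_len(k)], out_end[seq_len(k)], types[seq_len(k)],
             min_duration = dur_params$range[1])
}

#' Generate a plausible hypnogram
#'
#' Semi-Markov bout model over `W, N1, N2, N3, REM`: a wake period of
#' `latency_epochs` at the start and `end_wake_epochs` at the end, with
#' geometric bout lengths and a stage-transition matrix in between. The
#' last epoch may truncate at the recording end.
#'
#' @param duration_s recording duration (s); must cover at least one epoch.
#' @param stage_params list of `latency_epochs`, `end_wake_epochs`,
#'   `mean_bout_epochs` (named per stage) and `transition` (row-stochastic
#'   matrix over stages).
#' @param seed optional seed.
#' @return a `hypnogram`.
#' @export
generate_hypnogram <- function(duration_s,
                               stage_params = list(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  epoch_s <- 30
  if (duration_s < epoch_s) stop("generate_hypnogram: duration shorter than one epoch")
  p <- utils::modifyList(list(
    latency_epochs = 20L,
    end_wake_epochs = 2L,
    mean_bout_epochs = c(W = 2, N1 = 3, N2 = 18, N3 = 10, REM = 14),
    transition = matrix(c(
      #  W    N1    N2    N3   REM
      0.00, 0.70, 0.25, 0.00, 0.05,   # from W
      0.10, 0.00, 0.75, 0.05, 0.10,   # from N1
      0.10, 0.15, 0.00, 0.45, 0.30,   # from N2
      0.05, 0.10, 0.70, 0.00, 0.15,   # from N3
      0.20, 0.30, 0.50, 0.00, 0.00),  # from REM
      nrow = 5, byrow = TRUE, dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  ), stage_params)
  n_ep <- as.integer(ceiling(duration_s / epoch_s))
  stages <- rep("W", n_ep)
  first_sleep <- p$latency_epochs + 1L
  last_sleep <- n_ep - p$end_wake_epochs
  if (first_sleep <= last_sleep) {
    cur <- "N1"; i <- first_sleep
    while (i <= last_sleep) {
      mb <- p$mean_bout_epochs[[cur]]
      len <- 1L + stats::rgeom(1, prob = 1 / max(mb, 1))
      len <- min(len, last_sleep - i + 1L)
      stages[i:(i + len - 1L)] <- cur
      i <- i + len
      cur <- sample(SLEEP_STAGES, 1, prob = p$transition[cur, ])
    }
  }
  hypnogram(stages, epoch_s)
}

#' Generate a body-position track
#'
#' Exponential-length bouts (minimum one minute) over the configured
#' categories, one label per second.
#'
#' @param duration_s recording duration (s).
#' @param params list with `mean_bout_s`, `categories`, `probs`.
#' @param seed optional seed.
#' @return a `categorical_track`.
#' @export
generate_position_track <- function(duration_s,
                                    params = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(list(
    mean_bout_s = 2400,
    categories = c("supine", "prone", "left", "right"),
    probs = c(0.45, 0.1, 0.25, 0.2)), params)
  labels <- character(0)
  if (length(p$categories) == 1L) {
    labels <- rep(p$categories, duration_s)
  } else {
    cur <- sample(p$categories, 1, prob = p$probs)
    while (length(labels) < duration_s) {
      len <- max(60, round(stats::rexp(1, 1 / p$mean_bout_s)))
      labels <- c(labels, rep(cur, len))
      others <- setdiff(p$categories, cur)
      cur <- sample(others, 1, prob = p$probs[match(others, p$categories)])
    }
    labels <- labels[seq_len(duration_s)]
  }
  categorical_track(labels, p$categories)
}

# Event-linked heart-rate modulation (bpm) sampled on a 4 Hz grid:
# bradycardia dip during the event, tachycardia rebound decaying after it.
.hr_event_modulation <- function(duration_s, events, depth_bpm, grid_fs = 4) {
  n <- ceiling(duration_s * grid_fs)
  mod <- numeric(n)
  t <- (seq_len(n) - 1) / grid_fs
  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      s <- events$start_s[i]; e <- events$end_s[i]
      inside <- t >= s & t < e
      mod[inside] <- mod[inside] - depth_bpm * sin(pi * (t[inside] - s) / (e - s))
      after <- t >= e & t < e + 30
      mod[after] <- mod[after] + 0.8 * depth_bpm * exp(-(t[after] - e) / 8)
    }
  }
  mod
}

#' Generate beat times with event-linked cyclic heart-rate variation
#'
#' Integrates an instantaneous heart-rate function: baseline + slow drift +
#' respiratory sinus arrhythmia + a per-event bradycardia-tachycardia
#' excursion; optional premature (ectopic) beats are inserted at a configured
#' hourly rate by advancing isolated beats.
#'
#' @param duration_s recording duration (s).
#' @param hr_params list: `base_bpm` (30-180), `drift_bpm`, `rsa_bpm`,
#'   `resp_rate_hz`, `excursion_bpm`, `jitter_sd` (fractional RR jitter),
#'   `ectopic_per_h`.
#' @param events an `event_list` driving the excursions.
#' @param seed optional seed.
#' @return strictly increasing numeric vector of beat times (s).
#' @export
generate_beat_times <- function(duration_s, hr_params = list(),
                                events = event_list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(list(
    base_bpm = 62, drift_bpm = 2, rsa_bpm = 1.2, resp_rate_hz = 0.25,
    excursion_bpm = 10, jitter_sd = 0.01, ectopic_per_h = 0), hr_params)
  stopifnot(p$base_bpm >= 30, p$base_bpm <= 180)
  grid_fs <- 4
  mod <- .hr_event_modulation(duration_s, events, p$excursion_bpm, grid_fs)
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  n_est <- ceiling(duration_s * p$base_bpm / 60 * 1.5) + 10L
  beats <- numeric(n_est)
  t <- 0.3; k <- 0L
  while (t < duration_s) {
    gi <- min(floor(t * grid_fs) + 1L, length(mod))
    hr <- p$base_bpm +
      p$drift_bpm * sin(2 * pi * 0.003 * t + ph1) +
      p$rsa_bpm * sin(2 * pi * p$resp_rate_hz * t + ph2) +
      mod[gi]
    hr <- max(hr, 25)
    rr <- 60 / hr
    if (p$jitter_sd > 0) rr <- rr * (1 + stats::rnorm(1, 0, p$jitter_sd))
    k <- k + 1L
    beats[k] <- t
    t <- t + rr
  }
  beats <- beats[seq_len(k)]
  if (p$ectopic_per_h > 0 && k > 10L) {
    n_ect <- stats::rpois(1, p$ectopic_per_h * duration_s / 3600)
    if (n_ect > 0L) {
      cand <- sample(5:(k - 5L), min(n_ect, k - 10L))
      for (i in cand) {
        rr_prev <- beats[i] - beats[i - 1L]
        beats[i] <- beats[i] - 0.45 * rr_prev   # premature beat
      }
      beats <- sort(beats)
    }
  }
  beats
}

#' Render a synthetic ECG from beat times
#'
#' Gaussian-template QRS complexes placed at the beat times, with peak
#' amplitude modulated by the instantaneous respiration value (the EDR
#' substrate), plus baseline wander and white noise.
#'
#' @param beat_times beat times (s), within `[0, duration_s)`.
#' @param resp_signal a `sampled_signal` carrying respiration; may be `NULL`
#'   for unmodulated ECG.
#' @param params list: `fs` (>= 100 Hz), `duration_s`, `amp`, `mod_depth`,
#'   `qrs_sigma_s`, `wander_amp`, `wander_freq_hz`, `noise_sd`.
#' @return a `sampled_signal`.
#' @export
render_ecg <- function(beat_times, resp_signal = NULL, params = list()) {
  if (length(beat_times) == 0L) stop("render_ecg: empty beat list")
  p <- utils::modifyList(list(
    fs = 256, duration_s = ceiling(max(beat_times)) + 1,
    amp = 1, mod_depth = 0.2, qrs_sigma_s = 0.012,
    wander_amp = 0.05, wander_freq_hz = 0.33, noise_sd = 0.02), params)
  stopifnot(p$fs >= 100)
  n <- ceiling(p$duration_s * p$fs)
  v <- numeric(n)
  amps <- rep(p$amp, length(beat_times))
  if (!is.null(resp_signal) && p$mod_depth > 0) {
    rv <- stats::approx(signal_times(resp_signal), resp_signal$values,
                        xout = beat_times, rule = 2)$y
    scale <- max(abs(rv))
    if (scale > 0) amps <- p$amp * (1 + p$mod_depth * rv / scale)
  }
  w <- ceiling(4 * p$qrs_sigma_s * p$fs)
  rel_t <- (-w:w) / p$fs
  template <- exp(-0.5 * (rel_t / p$qrs_sigma_s)^2)
  for (i in seq_along(beat_times)) {
    c0 <- round(beat_times[i] * p$fs) + 1L
    lo <- max(1L, c0 - w); hi <- min(n, c0 + w)
    if (lo > hi) next
    # shift template by the sub-sample offset of the beat
    off <- beat_times[i] - (c0 - 1L) / p$fs
    tmpl <- exp(-0.5 * (((lo:hi - c0) / p$fs - off) / p$qrs_sigma_s)^2)
    v[lo:hi] <- v[lo:hi] + amps[i] * tmpl
  }
  tt <- (seq_len(n) - 1) / p$fs
  v <- v + p$wander_amp * sin(2 * pi * p$wander_freq_hz * tt)
  if (p$noise_sd > 0) v <- v + stats::rnorm(n, 0, p$noise_sd)
  sampled_signal(v, p$fs)
}

# Piecewise effort envelope: per-type depths inside events (mixed = central
# first half, obstructive second), short linear ramps at edges, and a
# recovery overshoot decaying after each event.
.effort_envelope <- function(t, events, depths, ramp_s = 1,
                             overshoot = 0.35, overshoot_tau = 8) {
  env <- rep(1, length(t))
  if (nrow(events) == 0L) return(env)
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]; e <- events$end_s[i]; ty <- events$type[i]
    if (is.na(ty)) ty <- "obstructive"
    target <- function(tt) {
      if (ty == "mixed") {
        mid <- (s + e) / 2
        ifelse(tt < mid, depths[["central"]], depths[["obstructive"]])
      } else rep(depths[[ty]], length(tt))
    }
    inside <- which(t >= s & t < e)
    if (length(inside)) {
      ti <- t[inside]
      d <- target(ti)
      ramp_in <- pmin((ti - s) / ramp_s, 1)
      ramp_out <- pmin((e - ti) / ramp_s, 1)
      ramp <- pmin(ramp_in, ramp_out)
      env[inside] <- pmin(env[inside], 1 + (d - 1) * ramp)
    }
    after <- which(t >= e & t < e + 5 * overshoot_tau)
    if (length(after)) {
      env[after] <- env[after] * (1 + overshoot * exp(-(t[after] - e) / overshoot_tau))
    }
  }
  env
}

#' Generate a respiratory-effort signal with event semantics
#'
#' Quasi-sinusoidal effort whose amplitude envelope is scaled inside events
#' according to clinical semantics: central apnea = effort largely absent,
#' obstructive = effort continues reduced, hypopnea = partial reduction,
#' mixed = central-then-obstructive halves; a recovery overshoot follows each
#' event.
#'
#' @param duration_s recording duration (s).
#' @param events an `event_list`.
#' @param resp_params list: `fs`, `rate_hz` (0.1-0.5), `rate_jitter`, `amp`,
#'   `amp_drift`, `depths` (named per type), `ramp_s`, `overshoot`,
#'   `overshoot_tau`, `noise_sd`.
#' @param seed optional seed.
#' @return a `sampled_signal`.
#' @export
generate_respiratory_effort <- function(duration_s, events = event_list(),
                                        resp_params = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(list(
    fs = 32, rate_hz = 0.25, rate_jitter = 0.03, amp = 1, amp_drift = 0.1,
    depths = c(hypopnea = 0.5, obstructive = 0.4, central = 0.05),
    ramp_s = 1, overshoot = 0.35, overshoot_tau = 8, noise_sd = 0.02), resp_params)
  stopifnot(p$rate_hz >= 0.1, p$rate_hz <= 0.5)
  n <- ceiling(duration_s * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  rate_inst <- p$rate_hz * (1 + p$rate_jitter * sin(2 * pi * 0.004 * t + ph1))
  phase <- 2 * pi * cumsum(rate_inst) / p$fs
  wave <- p$amp * (1 + p$amp_drift * sin(2 * pi * 0.0015 * t + ph2)) * sin(phase)
  env <- .effort_envelope(t, events, p$depths, p$ramp_s, p$overshoot,
                          p$overshoot_tau)
  v <- wave * env
  if (p$noise_sd > 0) v <- v + stats::rnorm(n, 0, p$noise_sd)
  sampled_signal(v, p$fs)
}

#' Generate one fully annotated synthetic subject
#'
#' Draws demographics and a class-conditional target AHI, builds the
#' hypnogram, plants events inside sleep, and renders the position track,
#' effort belt, beat times and respiration-modulated ECG. The reference AHI
#' is recomputed from the planted annotations and the hypnogram.
#'
#' @param config a [sim_config()].
#' @param seed integer seed fixing the whole record.
#' @param subject_id identifier string.
#' @param severity one of `names(config$severity_ranges)` or `NULL` to draw
#'   uniformly across classes.
#' @return a list of class `subject_record`.
#' @export
generate_subject <- function(config = sim_config(), seed = 1L,
                             subject_id = "S001", severity = NULL) {
  set.seed(seed)
  if (is.null(severity)) severity <- sample(names(config$severity_ranges), 1)
  rng <- config$severity_ranges[[severity]]
  target_ahi <- stats::runif(1, rng[1], rng[2])
  age <- stats::runif(1, config$age_range[1], config$age_range[2])
  bmi <- stats::runif(1, config$bmi_range[1], config$bmi_range[2])
  sex <- sample(c("M", "F"), 1)
  base_hr <- stats::runif(1, config$base_hr_range[1], config$base_hr_range[2])

  dur <- config$duration_s
  hyp <- generate_hypnogram(dur)
  mask <- sleep_mask(hyp, dur)
  if (!any(mask)) stop("generate_subject: hypnogram has no sleep")
  events <- plant_events(dur, target_ahi, mix = config$event_mix,
                         dur_params = list(meanlog = config$dur_meanlog,
                                           sdlog = config$dur_sdlog,
                                           range = config$dur_range),
                         sleep_mask = mask, min_gap_s = config$min_gap_s)
  position <- generate_position_track(dur)
  effort <- generate_respiratory_effort(
    dur, events,
    resp_params = list(fs = config$effort_fs, rate_hz = config$resp_rate_hz,
                       depths = config$effort_depths[SDB_TYPES[1:3]],
                       noise_sd = config$noise_sd))
  beat_times <- generate_beat_times(
    dur, hr_params = list(base_bpm = base_hr,
                          resp_rate_hz = config$resp_rate_hz,
                          excursion_bpm = config$hr_excursion_bpm,
                          ectopic_per_h = config$ectopic_per_h),
    events = events)
  ecg <- render_ecg(beat_times, effort,
                    params = list(fs = config$ecg_fs, duration_s = dur,
                                  mod_depth = config$qrs_mod_depth,
                                  noise_sd = config$noise_sd))
  tst_h <- total_sleep_time(hyp) / 3600
  rec <- structure(list(
    id = subject_id, age = age, bmi = bmi, sex = sex,
    severity = severity, target_ahi = target_ahi,
    ecg = ecg, effort = effort, beat_times = beat_times,
    events = events, hypnogram = hyp, position = position,
    lights_off_s = 0, lights_on_s = dur,
    reference_ahi = nrow(events) / tst_h,
    duration_s = dur, seed = seed), class = "subject_record")
  validate_subject_record(rec)
  rec
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s: %.1f h, %d events, AHI_ref %.1f (%s)\n",
              x$id, x$duration_s / 3600, nrow(x$events), x$reference_ahi,
              x$severity))
  invisible(x)
}

#' Audit the internal invariants of a subject record
#'
#' Checks strict beat ordering, event placement inside sleep, reference-AHI
#' consistency with the annotations and hypnogram, and the lights window.
#' Stops with a message on the first violation.
#'
#' @param rec a `subject_record`.
#' @return `TRUE` invisibly if all invariants hold.
#' @export
validate_subject_record <- function(rec) {
  stopifnot(inherits(rec, "subject_record"))
  if (any(diff(rec$beat_times) <= 0)) stop("record audit: beat times not strictly increasing")
  if (!(rec$lights_off_s < rec$lights_on_s && rec$lights_on_s <= rec$duration_s)) {
    stop("record audit: lights window invalid")
  }
  mask <- sleep_mask(rec$hypnogram, rec$duration_s)
  if (nrow(rec$events) > 0L) {
    for (i in seq_len(nrow(rec$events))) {
      secs <- floor(rec$events$start_s[i]):min(ceiling(rec$events$end_s[i]) - 1,
                                               rec$duration_s - 1)
      if (!all(mask[secs + 1L])) stop("record audit: event outside sleep")
    }
  }
  tst_h <- total_sleep_time(rec$hypnogram) / 3600
  if (tst_h <= 0) stop("record audit: zero total sleep time")
  if (abs(rec$reference_ahi - nrow(rec$events) / tst_h) > 1e-9) {
    stop("record audit: reference_ahi inconsistent with annotations")
  }
  invisible(TRUE)
}

#' Generate a severity-stratified synthetic cohort
#'
#' @param n total number of subjects.
#' @param severity_mix per-class counts (named or in the order
#'   normal/mild/moderate/severe); must sum to `n`.
#' @param seed root seed; per-subject seeds are drawn from it, so two root
#'   seeds give disjoint realizations.
#' @param config a [sim_config()].
#' @return list of `subject_record` with unique ids.
#' @export
generate_cohort <- function(n = 20, severity_mix = c(normal = 5, mild = 5,
                                                     moderate = 5, severe = 5),
                            seed = 1L, config = sim_config()) {
  stopifnot(sum(severity_mix) == n)
  classes <- rep(names(severity_mix), times = severity_mix)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    generate_subject(config, seed = sub_seeds[i],
                     subject_id = sprintf("S%03d", i), severity = classes[i])
  })
}
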