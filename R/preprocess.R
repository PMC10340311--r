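#' Beat series with validity flags
#'
#' @param times strictly increasing beat times (s).
#' @param valid logical vector, same length; `FALSE` marks artifact/ectopic
#'   beats.
#' @return object of class `beat_series`.
#' @export
beat_series <- function(times, valid = rep(TRUE, length(times))) {
  if (length(times) != length(valid)) stop("beat_series: flag length mismatch")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("beat_series: times must be strictly increasing")
  }
  structure(list(times = as.numeric(times), valid = as.logical(valid)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats (%d flagged invalid)\n",
              length(x$times), sum(!x$valid)))
  invisible(x)
}

#' Detect R peaks in an ECG signal
#'
#' A nonlinear transformation (derivative, squaring, moving-window
#' integration) followed by simple adaptive-threshold peak finding with a
#' refractory period; peak times are refined to sub-sample precision by
#' parabolic interpolation around the local ECG maximum.
#'
#' @param ecg a `sampled_signal` with `fs >= 100` and duration >= 10 s.
#' @param params list: `refractory_s` (default 0.25), `integration_s`
#'   moving-window length (default 0.1), `threshold_frac` of the robust
#'   signal level (default 0.25).
#' @return a `beat_series` (empty for flat/silent input).
#' @export
detect_r_peaks <- function(ecg, params = list()) {
  stopifnot(inherits(ecg, "sampled_signal"), ecg$fs >= 100)
  if (signal_duration(ecg) < 10) stop("detect_r_peaks: need at least 10 s of ECG")
  p <- utils::modifyList(list(refractory_s = 0.25, integration_s = 0.1,
                              threshold_frac = 0.25), params)
  fs <- ecg$fs
  x <- ecg$values
  # remove baseline wander before the energy transform
  bc <- butter_coefficients(2, 1 / (fs / 2), "high")
  xf <- filtfilt_zero_phase(bc$b, bc$a, x)
  d <- c(0, diff(xf)) * fs
  s <- d^2
  k <- max(3L, round(p$integration_s * fs))
  s <- as.numeric(stats::filter(c(rep(0, k - 1), s), rep(1 / k, k), sides = 1))
  s <- s[k:(k + length(x) - 1L)]
  level <- stats::quantile(s, 0.99)
  if (!is.finite(level) || level <= 1e-12) return(beat_series(numeric(0)))
  thr <- p$threshold_frac * level
  above <- s > thr
  if (!any(above)) return(beat_series(numeric(0)))
  # candidate regions of super-threshold energy
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  regs <- cbind(starts[r$values], ends[r$values])
  half <- round(0.06 * fs)
  times <- numeric(nrow(regs))
  for (i in seq_len(nrow(regs))) {
    lo <- max(1L, regs[i, 1] - half); hi <- min(length(x), regs[i, 2] + half)
    j <- lo + which.max(xf[lo:hi]) - 1L
    # parabolic refinement on the raw peak
    if (j > 1L && j < length(x)) {
      y1 <- xf[j - 1L]; y2 <- xf[j]; y3 <- xf[j + 1L]
      denom <- (y1 - 2 * y2 + y3)
      delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
    } else delta <- 0
    times[i] <- (j - 1L + delta) / fs
  }
  times <- sort(times)
  # enforce refractory period, keeping the larger peak
  keep <- rep(TRUE, length(times))
  amp_at <- function(t) xf[pmin(pmax(round(t * fs) + 1L, 1L), length(xf))]
  last <- 1L
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[last] < p$refractory_s) {
      if (amp_at(times[i]) > amp_at(times[last])) {
        keep[last] <- FALSE; last <- i
      } else keep[i] <- FALSE
    } else last <- i
  }
  beat_series(times[keep])
}

#' Flag ectopic beats by heart-rate acceleration limits
#'
#' A beat is flagged invalid when the interval it terminates differs from the
#' previous accepted interval by more than a relative limit (default 30%),
#' restricting the allowable beat-to-beat acceleration or deceleration of the
#' heart rate. Gradual drifts below the limit pass; times are never altered.
#'
#' @param beats a `beat_series` with at least 3 beats.
#' @param limits list with `rel_limit` (default 0.3).
#' @return a `beat_series` with updated validity flags.
#' @export
reject_ectopic <- function(beats, limits = list(rel_limit = 0.3)) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$times) < 3L) stop("reject_ectopic: need at least 3 beats")
  lim <- limits$rel_limit
  rr <- diff(beats$times)
  valid <- beats$valid
  ref <- rr[1]
  for (i in seq_along(rr)) {
    if (abs(rr[i] - ref) / ref > lim) {
      valid[i + 1L] <- FALSE          # beat terminating the deviant interval
    } else {
      ref <- rr[i]
    }
  }
  beat_series(beats$times, valid)
}

# Spans (start, end in s) enclosing invalid beats: the full inter-beat span
# from the preceding to the following beat.
.invalid_spans <- function(beats) {
  bad <- which(!beats$valid)
  if (length(bad) == 0L) return(NULL)
  n <- length(beats$times)
  lo <- beats$times[pmax(bad - 1L, 1L)]
  hi <- beats$times[pmin(bad + 1L, n)]
  cbind(lo, hi)
}

#' Interpolated 4 Hz RR-interval series
#'
#' RR intervals between valid beats are attached to the interval midpoints,
#' linearly interpolated and resampled at `fs`; samples inside the inter-beat
#' span enclosing any invalid beat are set exactly to 0, marking them as
#' missing for the downstream model.
#'
#' @param beats a `beat_series` with >= 2 valid beats.
#' @param fs output rate (default 4 Hz).
#' @param duration_s output span in seconds (default: last beat time).
#' @return a `sampled_signal` of RR values in seconds (0 where excluded),
#'   length `ceiling(duration_s * fs)`.
#' @export
rr_series <- function(beats, fs = 4, duration_s = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  tv <- beats$times[beats$valid]
  if (length(tv) < 2L) stop("rr_series: need at least 2 valid beats")
  if (is.null(duration_s)) duration_s <- max(beats$times)
  # intervals between consecutive valid beats, at their midpoints
  rr <- diff(tv)
  mid <- (tv[-1] + tv[-length(tv)]) / 2
  n <- ceiling(duration_s * fs)
  t_out <- (seq_len(n) - 1) / fs
  vals <- stats::approx(mid, rr, xout = t_out, rule = 2)$y
  spans <- .invalid_spans(beats)
  if (!is.null(spans)) {
    for (i in seq_len(nrow(spans))) {
      vals[t_out >= spans[i, 1] & t_out <= spans[i, 2]] <- 0
    }
  }
  sampled_signal(vals, fs)
}

# Phase-space descriptor of one QRS complex: area swept by the 2-D
# delay-embedded trajectory (shoelace formula). Scales monotonically with
# QRS amplitude, so respiration-driven amplitude modulation survives.
.qrs_phase_space_area <- function(seg, delay_n) {
  m <- length(seg) - delay_n
  if (m < 3L) return(NA_real_)
  x <- seg[seq_len(m)]
  y <- seg[seq_len(m) + delay_n]
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

#' Extract ECG-derived respiration (EDR) by phase-space reconstruction
#'
#' For each valid beat, the QRS complex (window +/- `halfwin_s`) is
#' delay-embedded in 2-D and summarized by the swept trajectory area; the
#' per-beat series is linearly interpolated to `fs` and linearly detrended.
#'
#' @param ecg a `sampled_signal`.
#' @param beats a `beat_series` aligned to `ecg`.
#' @param params list: `delay_s` (default 0.02), `halfwin_s` (default 0.06),
#'   `fs` (default 4).
#' @param duration_s output span (default: ECG duration).
#' @return a `sampled_signal` at `fs`.
#' @export
extract_edr <- function(ecg, beats, params = list(), duration_s = NULL) {
  stopifnot(inherits(ecg, "sampled_signal"), inherits(beats, "beat_series"))
  p <- utils::modifyList(list(delay_s = 0.02, halfwin_s = 0.06, fs = 4), params)
  if (is.null(duration_s)) duration_s <- signal_duration(ecg)
  fs_in <- ecg$fs
  delay_n <- max(1L, round(p$delay_s * fs_in))
  half_n <- round(p$halfwin_s * fs_in)
  tv <- beats$times[beats$valid]
  vals <- rep(NA_real_, length(tv))
  n_sig <- length(ecg$values)
  skipped <- 0L
  for (i in seq_along(tv)) {
    c0 <- round((tv[i] - ecg$t0) * fs_in) + 1L
    lo <- c0 - half_n; hi <- c0 + half_n + delay_n
    if (lo < 1L || hi > n_sig) { skipped <- skipped + 1L; next }
    vals[i] <- .qrs_phase_space_area(ecg$values[lo:hi], delay_n)
  }
  if (skipped > 0L) {
    message(sprintf("extract_edr: skipped %d beats with windows outside the signal", skipped))
  }
  ok <- !is.na(vals)
  if (sum(ok) < 2L) stop("extract_edr: fewer than 2 usable beats")
  n <- ceiling(duration_s * p$fs)
  t_out <- (seq_len(n) - 1) / p$fs
  y <- stats::approx(tv[ok], vals[ok], xout = t_out, rule = 2)$y
  # linear detrend
  fit <- stats::lm.fit(cbind(1, t_out), y)
  sampled_signal(y - fit$fitted.values + 0, p$fs)
}

#' Preprocess a raw respiratory-effort signal
#'
#' Anti-aliased resampling to `fs` (4 Hz Nyquist enforces removal of
#' components above 2 Hz) followed by a zero-phase 4th-order Butterworth
#' high-pass at `highpass_hz` to remove low-frequency baseline drift.
#'
#' @param re_raw a `sampled_signal` with `fs >= 4`.
#' @param fs output rate (default 4 Hz).
#' @param highpass_hz high-pass cutoff (default 0.05 Hz).
#' @return a `sampled_signal` at `fs`.
#' @export
preprocess_effort <- function(re_raw, fs = 4, highpass_hz = 0.05) {
  stopifnot(inherits(re_raw, "sampled_signal"), re_raw$fs >= 4)
  x <- if (re_raw$fs == fs) re_raw else resample_signal(re_raw, fs)
  bc <- butter_coefficients(4, highpass_hz / (fs / 2), "high")
  sampled_signal(filtfilt_zero_phase(bc$b, bc$a, x$values), fs, x$t0)
}

#' Run the full preprocessing chain on a subject record
#'
#' Detects beats from the ECG, rejects ectopic beats, and derives the three
#' 4 Hz model inputs (RR series, EDR, processed effort) over a common span.
#'
#' @param rec a `subject_record`.
#' @param fs common output rate (default 4 Hz).
#' @return list with `rr`, `edr`, `re` (`sampled_signal`s of equal length)
#'   and `beats` (the flagged `beat_series`).
#' @export
preprocess_record <- function(rec, fs = 4) {
  stopifnot(inherits(rec, "subject_record"))
  beats <- detect_r_peaks(rec$ecg)
  beats <- reject_ectopic(beats)
  dur <- rec$duration_s
  rr <- rr_series(beats, fs = fs, duration_s = dur)
  edr <- extract_edr(rec$ecg, beats, params = list(fs = fs), duration_s = dur)
  re <- preprocess_effort(rec$effort, fs = fs)
  n <- min(length(rr$values), length(edr$values), length(re$values))
  list(rr = sampled_signal(rr$values[seq_len(n)], fs),
       edr = sampled_signal(edr$values[seq_len(n)], fs),
       re = sampled_signal(re$values[seq_len(n)], fs),
       beats = beats)
}
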