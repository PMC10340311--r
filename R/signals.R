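#' Uniformly sampled signal
#'
#' Lightweight container for a uniformly sampled channel: numeric values, a
#' sampling rate `fs` in Hz and a start time `t0` in seconds relative to the
#' recording start. All pipeline stages exchange signals in this form.
#'
#' @param values numeric vector of samples; must be finite and non-empty.
#' @param fs sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds (default 0).
#' @return an object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("sampled_signal: need at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("sampled_signal: fs must be a single positive number")
  }
  if (!all(is.finite(values))) stop("sampled_signal: values must be finite")
  structure(list(values = values, fs = fs, t0 = t0), class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz, t0 = %gs, span %.1fs\n",
              length(x$values), x$fs, x$t0, length(x$values) / x$fs))
  invisible(x)
}

#' Sample times of a sampled signal
#' @param x a `sampled_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  x$t0 + (seq_along(x$values) - 1L) / x$fs
}

#' Duration of a sampled signal in seconds
#' @param x a `sampled_signal`.
#' @export
signal_duration <- function(x) length(x$values) / x$fs

# ---------------------------------------------------------------------------
# IIR filter design and zero-phase filtering.
# No DSP package is available in this stack, so a minimal Butterworth design
# (analog prototype -> bilinear transform) and filtfilt are provided here.
# ---------------------------------------------------------------------------

# Polynomial coefficients (descending powers) from roots, real part taken.
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  Re(p)
}

#' Butterworth digital filter coefficients
#'
#' Designs an order-`n` digital Butterworth low- or high-pass filter via the
#' bilinear transform with frequency prewarping. `w` is the cutoff as a
#' fraction of the Nyquist frequency (as in common DSP toolboxes).
#'
#' @param n filter order.
#' @param w normalized cutoff in (0, 1) (1 = Nyquist).
#' @param type `"low"` or `"high"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_coefficients <- function(n, w, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, w > 0, w < 1)
  # analog lowpass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2                      # bilinear transform with fs = 2
  warped <- 2 * fs2 * tan(pi * w / fs2)
  if (type == "low") {
    p <- warped * p
    z_digital <- rep(-1 + 0i, n)
  } else {
    p <- warped / p
    z_digital <- rep(1 + 0i, n)
  }
  # bilinear transform of poles
  p_digital <- (2 * fs2 + p) / (2 * fs2 - p)
  b <- .poly_from_roots(z_digital)
  a <- .poly_from_roots(p_digital)
  # normalize gain: unity at DC (lowpass) or Nyquist (highpass)
  zref <- if (type == "low") 1 else -1
  zp <- zref^(seq_along(a) - 1)
  gain <- sum(a * zp) / sum(b * zp)
  list(b = b * gain, a = a)
}

# Direct-form IIR filter, zero initial conditions; C-speed via stats::filter.
.iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  # moving-average part
  xp <- c(rep(0, nb - 1L), x)
  y <- stats::filter(xp, b, method = "convolution", sides = 1)
  y <- as.numeric(y)[nb:length(xp)]
  # autoregressive part
  if (length(a) > 1L) {
    y <- as.numeric(stats::filter(y, -a[-1], method = "recursive"))
  }
  y
}

#' Zero-phase forward-backward filtering
#'
#' Applies an IIR filter forward and backward (squared magnitude response,
#' zero phase) with odd-reflection edge padding, so filtered features stay
#' aligned with event annotations.
#'
#' @param b,a filter coefficients as from [butter_coefficients()].
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x) {
  n <- length(x)
  pad <- min(max(100L, 12L * (max(length(a), length(b)) - 1L)), n - 1L)
  one_pass <- function(v) {
    # start from the edge value so zero initial conditions see no step
    edge <- v[1]
    .iir_filter(b, a, v - edge) + edge * .dc_gain(b, a)
  }
  if (pad < 1L) return(one_pass(x))
  pre  <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(pre, x, post)
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

.dc_gain <- function(b, a) sum(b) / sum(a)

# Windowed-sinc (Hamming) FIR low-pass taps; fc as fraction of Nyquist.
.fir_lowpass_taps <- function(fc, ntaps = 127L) {
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  m <- (ntaps - 1L) / 2L
  k <- seq(-m, m)
  h <- fc * sinc_fun(fc * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)
  h <- h * w
  h / sum(h)
}

sinc_fun <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Anti-aliased resampling of a sampled signal
#'
#' Low-pass filters with a windowed-sinc FIR at 90% of the target Nyquist
#' (only when downsampling), then linearly interpolates onto the new uniform
#' grid. Downsampling to `fs_out` therefore removes components above
#' `fs_out / 2` by construction.
#'
#' @param x a `sampled_signal`.
#' @param fs_out target rate in Hz.
#' @param ntaps FIR length for the anti-alias filter.
#' @return a `sampled_signal` at `fs_out` spanning the same interval.
#' @export
resample_signal <- function(x, fs_out, ntaps = 127L) {
  stopifnot(inherits(x, "sampled_signal"), fs_out > 0)
  v <- x$values
  if (fs_out < x$fs) {
    fc <- 0.9 * fs_out / x$fs        # fraction of input Nyquist
    h <- .fir_lowpass_taps(fc, ntaps)
    m <- (length(h) - 1L) / 2L
    vp <- c(rep(v[1], m), v, rep(v[length(v)], m))
    v <- as.numeric(stats::filter(vp, h, method = "convolution", sides = 2))
    v <- v[(m + 1L):(m + length(x$values))]
  }
  dur <- length(x$values) / x$fs
  n_out <- ceiling(dur * fs_out)
  t_new <- (seq_len(n_out) - 1L) / fs_out
  t_old <- (seq_along(v) - 1L) / x$fs
  out <- stats::approx(t_old, v, xout = pmin(t_new, max(t_old)), rule = 2)$y
  sampled_signal(out, fs_out, x$t0)
}

#' Dominant spectral frequency in a band
#'
#' Periodogram-based peak frequency, used as an oracle for respiration-carrying
#' signals (EDR, effort).
#'
#' @param values numeric vector (uniformly sampled).
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, search band in Hz.
#' @return peak frequency in Hz.
#' @export
spectral_peak <- function(values, fs, band = c(0.05, 1)) {
  values <- values - mean(values)
  sp <- stats::spec.pgram(stats::ts(values, frequency = fs),
                          taper = 0, detrend = TRUE, plot = FALSE)
  keep <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(keep)) stop("spectral_peak: band contains no frequencies")
  sp$freq[keep][which.max(sp$spec[keep])]
}
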