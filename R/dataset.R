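#' "Soft" min-max normalization of a segment channel
#'
#' Maps the 5th percentile to 0 and the 95th percentile to 1 (percentiles by
#' linear interpolation between order statistics); values outside `[0, 1]`
#' are allowed, preserving extremes such as post-apnea recovery overshoots.
#' A degenerate channel (p95 == p5) becomes all 0.5 with a warning.
#'
#' @param x numeric vector of finite values.
#' @return normalized numeric vector.
#' @export
soft_minmax <- function(x) {
  if (!all(is.finite(x))) stop("soft_minmax: values must be finite")
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[2] - q[1] <= .Machine$double.eps * max(abs(q), 1)) {
    warning("soft_minmax: degenerate segment (p95 == p5); returning 0.5")
    return(rep(0.5, length(x)))
  }
  (x - q[1]) / (q[2] - q[1])
}

#' 1 Hz binary target for a window
#'
#' Second `t` (0-based within the window) is labeled 1 iff `[t, t+1)`
#' overlaps any annotated event.
#'
#' @param events an `event_list`.
#' @param window_start window start time (s).
#' @param window_s window length in seconds (default 300).
#' @return integer vector of 0/1 of length `window_s`.
#' @export
build_target <- function(events, window_start, window_s = 300) {
  target <- integer(window_s)
  if (nrow(events) == 0L) return(target)
  sec_start <- window_start + seq_len(window_s) - 1L
  for (i in seq_len(nrow(events))) {
    hit <- events$start_s[i] < sec_start + 1 & events$end_s[i] > sec_start
    target[hit] <- 1L
  }
  target
}

#' Sample weights for a binary target
#'
#' Class-imbalance weighting: label 0 -> 1, label 1 -> 10.
#'
#' @param target integer 0/1 vector.
#' @param w1 weight for label 1 (default 10).
#' @return numeric weights, same length.
#' @export
make_weights <- function(target, w1 = 10) {
  ifelse(target == 1L, w1, 1)
}

#' Validate a segment's structural invariants
#' @param seg a segment as produced by [segment_record()].
#' @param input_len,target_len expected lengths.
#' @return TRUE invisibly, or an error.
#' @export
validate_segment <- function(seg, input_len = 1200L, target_len = 300L) {
  stopifnot(is.matrix(seg$inputs), nrow(seg$inputs) == input_len,
            ncol(seg$inputs) == 2L,
            length(seg$target) == target_len,
            length(seg$weights) == target_len,
            all(seg$weights[seg$target == 1L] == 10),
            all(seg$weights[seg$target == 0L] == 1))
  invisible(TRUE)
}

#' Segment a night into normalized model inputs
#'
#' Cuts 5-minute windows starting every 3 minutes (2-minute overlap) wholly
#' inside the lights-off window, normalizes each channel with
#' [soft_minmax()], and attaches 1 Hz targets and sample weights. The window
#' grid is anchored at `lights_off_s`; a trailing partial window is dropped.
#'
#' @param channels list of two `sampled_signal`s at 4 Hz and equal length;
#'   channel order is (RR, respiration surrogate).
#' @param events an `event_list` (annotations).
#' @param lights_off_s,lights_on_s usable recording window (s).
#' @param window_s,stride_s window length and stride (defaults 300/180 s).
#' @return list of segments, each with `inputs` (1200 x 2), `target` (300),
#'   `weights` (300), `start_s`; empty list with a warning when the usable
#'   span is shorter than one window.
#' @export
segment_record <- function(channels, events, lights_off_s = 0,
                           lights_on_s = NULL, window_s = 300, stride_s = 180) {
  stopifnot(length(channels) == 2L,
            all(vapply(channels, inherits, TRUE, "sampled_signal")))
  fs <- channels[[1]]$fs
  stopifnot(channels[[2]]$fs == fs,
            length(channels[[1]]$values) == length(channels[[2]]$values))
  dur <- length(channels[[1]]$values) / fs
  if (is.null(lights_on_s)) lights_on_s <- dur
  lights_on_s <- min(lights_on_s, dur)
  usable <- lights_on_s - lights_off_s
  if (usable < window_s) {
    warning("segment_record: usable span shorter than one window; no segments")
    return(list())
  }
  starts <- seq(lights_off_s, lights_on_s - window_s, by = stride_s)
  npw <- as.integer(window_s * fs)
  lapply(starts, function(s0) {
    i0 <- round(s0 * fs)
    idx <- (i0 + 1L):(i0 + npw)
    inputs <- cbind(soft_minmax(channels[[1]]$values[idx]),
                    soft_minmax(channels[[2]]$values[idx]))
    target <- build_target(events, s0, window_s)
    list(inputs = inputs, target = target,
         weights = make_weights(target), start_s = s0)
  })
}

# round to nearest with ties toward the smaller count
.round_half_down <- function(x) ceiling(x - 0.5)

#' Severity-stratified train/validation/test split
#'
#' Within each severity class, `test_frac` of subjects (round to nearest,
#' ties downward) go to the test set; of the remainder, `val_frac` go to
#' validation and the rest to training. The shuffle is seeded.
#'
#' @param severity named character vector: subject id -> severity class.
#' @param test_frac fraction for testing (default 0.25).
#' @param val_frac fraction of the remainder for validation (default 0.25).
#' @param seed integer seed.
#' @return named character vector: subject id -> `"train"`, `"validation"`
#'   or `"test"`.
#' @export
stratified_split <- function(severity, test_frac = 0.25, val_frac = 0.25,
                             seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, val_frac > 0, val_frac < 1)
  set.seed(seed)
  out <- character(0)
  for (cls in unique(severity)) {
    ids <- names(severity)[severity == cls]
    if (length(ids) == 0L) { warning("stratified_split: empty class ", cls); next }
    ids <- sample(ids)
    n <- length(ids)
    n_test <- .round_half_down(n * test_frac)
    n_val <- .round_half_down((n - n_test) * val_frac)
    assign <- rep("train", n)
    if (n_test > 0) assign[seq_len(n_test)] <- "test"
    if (n_val > 0) assign[n_test + seq_len(n_val)] <- "validation"
    names(assign) <- ids
    out <- c(out, assign)
  }
  out[names(severity)[names(severity) %in% names(out)]]
}

#' Build segments for a preprocessed subject under one input pairing
#'
#' @param prep output of [preprocess_record()].
#' @param rec the originating `subject_record` (for events and lights).
#' @param pairing `"rr_re"` (RR + respiratory effort) or `"rr_edr"`
#'   (RR + ECG-derived respiration).
#' @return list of segments (see [segment_record()]).
#' @export
segments_for_pairing <- function(prep, rec, pairing = c("rr_re", "rr_edr")) {
  pairing <- match.arg(pairing)
  second <- if (pairing == "rr_re") prep$re else prep$edr
  segment_record(list(prep$rr, second), rec$events,
                 lights_off_s = rec$lights_off_s,
                 lights_on_s = rec$lights_on_s)
}
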