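#' Whole-night 1 Hz prediction series
#'
#' @param probs numeric probabilities in `[0, 1]`, one per second from
#'   recording start.
#' @param scored logical, same length; `FALSE` marks seconds not covered by
#'   any segment's central interval (their probability is 0 by convention).
#' @param subject_id identifier.
#' @param wake_masked has wake masking been applied.
#' @return object of class `night_prediction`.
#' @export
night_prediction <- function(probs, scored = rep(TRUE, length(probs)),
                             subject_id = NA_character_, wake_masked = FALSE) {
  stopifnot(length(scored) == length(probs),
            all(probs >= 0 & probs <= 1))
  if (any(probs[!scored] != 0)) stop("night_prediction: unscored seconds must be 0")
  structure(list(probs = probs, scored = scored, subject_id = subject_id,
                 wake_masked = wake_masked), class = "night_prediction")
}

#' @export
print.night_prediction <- function(x, ...) {
  cat(sprintf("<night_prediction> %s: %d s (%d scored)%s\n",
              x$subject_id, length(x$probs), sum(x$scored),
              if (x$wake_masked) ", wake-masked" else ""))
  invisible(x)
}

#' Stitch per-segment probabilities into a night series
#'
#' Each second takes the probability from the unique segment whose central
#' 3-minute interval `[start+60, start+240)` contains it; the first and last
#' minute of every segment are discarded for context. Seconds covered by no
#' central interval are set to 0 and marked unscored. Segment starts must lie
#' on the 180-s grid so central intervals tile exactly.
#'
#' @param seg_probs matrix `n_segments x 300` of 1 Hz probabilities.
#' @param starts segment start times (s).
#' @param duration_s night duration (s); default covers the last segment.
#' @param subject_id identifier.
#' @return a `night_prediction`.
#' @export
stitch_predictions <- function(seg_probs, starts, duration_s = NULL,
                               subject_id = NA_character_) {
  stopifnot(nrow(seg_probs) == length(starts), ncol(seg_probs) == 300L)
  if (length(starts) > 1L) {
    rel <- (starts - starts[1])
    if (any(rel %% 180 != 0) || anyDuplicated(starts)) {
      stop("stitch_predictions: segment starts violate the 180-s grid")
    }
  }
  if (is.null(duration_s)) duration_s <- max(starts) + 300
  n <- as.integer(ceiling(duration_s))
  probs <- numeric(n)
  scored <- logical(n)
  for (i in order(starts)) {
    sec <- (starts[i] + 60):(starts[i] + 239)
    keep <- sec >= 0 & sec < n
    sec <- sec[keep]
    if (any(scored[sec + 1L])) {
      stop("stitch_predictions: overlapping central intervals")
    }
    probs[sec + 1L] <- seg_probs[i, 61:240][keep]
    scored[sec + 1L] <- TRUE
  }
  night_prediction(probs, scored, subject_id)
}

#' Zero event probabilities during wake
#'
#' @param pred a `night_prediction`.
#' @param hyp a `hypnogram` covering the prediction span.
#' @return the wake-masked `night_prediction`.
#' @export
mask_wake <- function(pred, hyp) {
  stopifnot(inherits(pred, "night_prediction"), inherits(hyp, "hypnogram"))
  n <- length(pred$probs)
  if (length(hyp$stages) * hyp$epoch_s < n) {
    stop("mask_wake: hypnogram does not cover the prediction span")
  }
  st <- stage_at(hyp, seq_len(n) - 1L)
  probs <- pred$probs
  probs[st == "W"] <- 0
  night_prediction(probs, pred$scored, pred$subject_id, wake_masked = TRUE)
}

#' Binarize a night prediction into detected events
#'
#' Maximal runs of scored seconds with probability strictly greater than the
#' threshold become events `[run_start, run_end + 1)`. No minimum duration is
#' imposed and close events are not merged. Unscored seconds cannot belong to
#' an event.
#'
#' @param pred a `night_prediction`.
#' @param threshold detection threshold in (0, 1).
#' @return an `event_list` of untyped detections.
#' @export
binarize_events <- function(pred, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  above <- pred$probs > threshold & pred$scored
  if (!any(above)) return(event_list())
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  event_list(starts[r$values], ends[r$values], NA_character_)
}

.check_sorted <- function(ev, what) {
  if (nrow(ev) > 1L && any(diff(ev$start_s) < 0)) {
    stop(sprintf("match_events: %s events not sorted", what))
  }
}

#' Match detected to annotated events (strict first-overlap rule)
#'
#' Greedy one-to-one temporal matching: annotated events are scanned in time
#' order and each is credited to its earliest-starting overlapping detected
#' event that is not already matched. Matched pairs are TPs; remaining
#' detections are FPs; annotated events with no credited detection are FNs.
#' A second detection overlapping an already-credited annotation therefore
#' counts as FP, and the second annotation spanned by a single detection
#' counts as FN.
#'
#' @param detected,annotated `event_list`s (sorted; half-open intervals).
#' @return list of class `match_counts`: `tp`, `fp`, `fn`,
#'   `ann_matched` (logical per annotated event), `det_matched`.
#' @export
match_events_strict <- function(detected, annotated) {
  .check_sorted(detected, "detected"); .check_sorted(annotated, "annotated")
  nd <- nrow(detected); na <- nrow(annotated)
  det_matched <- rep(FALSE, nd)
  ann_matched <- rep(FALSE, na)
  for (i in seq_len(na)) {
    for (j in seq_len(nd)) {
      if (det_matched[j]) next
      if (detected$start_s[j] >= annotated$end_s[i]) break
      if (detected$end_s[j] > annotated$start_s[i]) {
        det_matched[j] <- TRUE
        ann_matched[i] <- TRUE
        break
      }
    }
  }
  structure(list(tp = sum(det_matched), fp = nd - sum(det_matched),
                 fn = na - sum(ann_matched),
                 ann_matched = ann_matched, det_matched = det_matched,
                 rule = "strict"), class = "match_counts")
}

#' Match detected to annotated events (any-overlap rule)
#'
#' Every detected event overlapping at least one annotated event is a TP;
#' the rest are FPs. An annotated event with no overlapping detection is an
#' FN.
#'
#' @param detected,annotated `event_list`s (sorted).
#' @return a `match_counts` (see [match_events_strict()]).
#' @export
match_events_olsen <- function(detected, annotated) {
  .check_sorted(detected, "detected"); .check_sorted(annotated, "annotated")
  nd <- nrow(detected); na <- nrow(annotated)
  overlap <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2
  det_matched <- vapply(seq_len(nd), function(j) {
    any(overlap(detected$start_s[j], detected$end_s[j],
                annotated$start_s, annotated$end_s))
  }, TRUE)
  ann_matched <- vapply(seq_len(na), function(i) {
    any(overlap(detected$start_s, detected$end_s,
                annotated$start_s[i], annotated$end_s[i]))
  }, TRUE)
  if (nd == 0L) det_matched <- logical(0)
  if (na == 0L) ann_matched <- logical(0)
  structure(list(tp = sum(det_matched), fp = nd - sum(det_matched),
                 fn = sum(!ann_matched),
                 ann_matched = ann_matched, det_matched = det_matched,
                 rule = "olsen"), class = "match_counts")
}

#' Clip events to the scored span of a prediction
#'
#' Annotation seconds outside segment coverage can be neither credited nor
#' penalized; events are intersected with the scored mask and fragments
#' shorter than `min_keep_s` are dropped.
#'
#' @param events an `event_list`.
#' @param pred a `night_prediction`.
#' @param min_keep_s drop clipped fragments of this length or shorter
#'   (default 0: keep any fragment of positive length, since detection
#'   imposes no minimum event duration).
#' @return an `event_list`.
#' @export
clip_events_to_scored <- function(events, pred, min_keep_s = 0) {
  if (nrow(events) == 0L) return(events)
  n <- length(pred$scored)
  keep_s <- numeric(0); keep_e <- numeric(0); keep_t <- character(0)
  r <- rle(pred$scored)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  spans <- cbind(starts[r$values], ends[r$values])
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]; e <- events$end_s[i]
    for (k in seq_len(nrow(spans))) {
      cs <- max(s, spans[k, 1]); ce <- min(e, spans[k, 2])
      if (ce - cs > min_keep_s) {
        keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce)
        keep_t <- c(keep_t, events$type[i])
      }
    }
  }
  event_list(keep_s, keep_e, keep_t)
}

#' Select the detection threshold on validation nights
#'
#' Sweeps the grid 0.004 to 0.996 in steps of 0.004 (249 points), computes
#' the pooled strict-rule F1 over all validation nights at each point, and
#' returns the grid argmax (ties resolve to the smallest threshold).
#'
#' @param nights list of lists with elements `pred` (a `night_prediction`)
#'   and `annotated` (an `event_list`).
#' @param grid threshold grid.
#' @return list of class `threshold_selection`: `grid`, `f1`, `threshold`.
#' @export
select_threshold <- function(nights, grid = 0.004 * seq_len(249)) {
  stopifnot(length(nights) >= 1)
  n_events <- sum(vapply(nights, function(x) nrow(x$annotated), 0L))
  if (n_events == 0L) stop("select_threshold: no annotated events in validation nights")
  f1 <- vapply(grid, function(tau) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (nt in nights) {
      det <- binarize_events(nt$pred, tau)
      ann <- clip_events_to_scored(nt$annotated, nt$pred)
      m <- match_events_strict(det, ann)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    if (tp == 0L) return(0)
    prec <- tp / (tp + fp); sens <- tp / (tp + fn)
    2 * prec * sens / (prec + sens)
  }, 0.0)
  if (max(f1) == 0) {
    warning("select_threshold: no threshold detects anything; returning smallest")
    return(structure(list(grid = grid, f1 = f1, threshold = grid[1]),
                     class = "threshold_selection"))
  }
  structure(list(grid = grid, f1 = f1, threshold = grid[which.max(f1)]),
            class = "threshold_selection")
}

#' Per-subject and pooled detection metrics
#'
#' Sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)` and their harmonic-mean
#' F1, as mean +/- SD across subjects and pooled from summed counts.
#' Undefined per-subject ratios (0/0) are excluded from the mean with a
#' warning.
#'
#' @param matches list of `match_counts`, one per night.
#' @return list of class `detection_metrics` with `per_subject` data.frame
#'   and `mean`, `sd`, `pooled` named vectors.
#' @export
detection_metrics <- function(matches) {
  stopifnot(length(matches) >= 1)
  per <- do.call(rbind, lapply(matches, function(m) {
    sens <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
    prec <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
    f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0) {
      2 * sens * prec / (sens + prec)
    } else NA_real_
    data.frame(tp = m$tp, fp = m$fp, fn = m$fn,
               sensitivity = sens, precision = prec, f1 = f1)
  }))
  if (anyNA(per[, c("sensitivity", "precision", "f1")])) {
    warning("detection_metrics: undefined per-subject ratios excluded from the mean")
  }
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  pooled_sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  pooled_prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  pooled_f1 <- if (!is.na(pooled_sens) && !is.na(pooled_prec) &&
                   pooled_sens + pooled_prec > 0) {
    2 * pooled_sens * pooled_prec / (pooled_sens + pooled_prec)
  } else NA_real_
  cols <- c("sensitivity", "precision", "f1")
  structure(list(
    per_subject = per,
    mean = colMeans(per[, cols], na.rm = TRUE),
    sd = apply(per[, cols], 2, stats::sd, na.rm = TRUE),
    pooled = c(sensitivity = pooled_sens, precision = pooled_prec,
               f1 = pooled_f1)), class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> pooled sens %.3f prec %.3f F1 %.3f (n=%d)\n",
              x$pooled["sensitivity"], x$pooled["precision"], x$pooled["f1"],
              nrow(x$per_subject)))
  invisible(x)
}

#' Pooled detection rate per annotated event type
#'
#' @param matches list of `match_counts` (strict rule).
#' @param annotated list of `event_list`s aligned with `matches`.
#' @return named numeric vector of per-type sensitivities.
#' @export
detection_rate_by_type <- function(matches, annotated) {
  stopifnot(length(matches) == length(annotated))
  types <- character(0); hit <- logical(0)
  for (i in seq_along(matches)) {
    stopifnot(length(matches[[i]]$ann_matched) == nrow(annotated[[i]]))
    types <- c(types, annotated[[i]]$type)
    hit <- c(hit, matches[[i]]$ann_matched)
  }
  present <- intersect(SDB_TYPES, unique(types))
  vapply(present, function(ty) mean(hit[types == ty]), 0.0)
}

#' Detection rate stratified by sleep stage or body position
#'
#' Each annotated event is assigned the category at its start second; the
#' per-category sensitivity is returned (categories with no events omitted).
#'
#' @param matches list of `match_counts`.
#' @param annotated list of `event_list`s.
#' @param tracks list of `hypnogram` or `categorical_track`, one per night.
#' @return named numeric vector of sensitivities.
#' @export
stratified_detection_rate <- function(matches, annotated, tracks) {
  stopifnot(length(matches) == length(annotated),
            length(matches) == length(tracks))
  cats <- character(0); hit <- logical(0)
  for (i in seq_along(matches)) {
    ann <- annotated[[i]]
    if (nrow(ann) == 0L) next
    tk <- tracks[[i]]
    lab <- if (inherits(tk, "hypnogram")) {
      stage_at(tk, ann$start_s)
    } else if (inherits(tk, "categorical_track")) {
      if (length(tk$labels) == 0L) stop("stratified_detection_rate: empty track")
      tk$labels[pmin(floor(ann$start_s) + 1L, length(tk$labels))]
    } else stop("stratified_detection_rate: unsupported track type")
    cats <- c(cats, lab)
    hit <- c(hit, matches[[i]]$ann_matched)
  }
  if (length(cats) == 0L) stop("stratified_detection_rate: no events")
  out <- tapply(hit, cats, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Mean length of detected versus missed annotated events
#'
#' @param matches list of `match_counts`.
#' @param annotated list of `event_list`s.
#' @return named numeric vector `detected`, `missed` (NA when a group is
#'   empty).
#' @export
event_length_summary <- function(matches, annotated) {
  stopifnot(length(matches) == length(annotated))
  lens <- numeric(0); hit <- logical(0)
  for (i in seq_along(matches)) {
    ann <- annotated[[i]]
    if (nrow(ann) == 0L) next
    lens <- c(lens, ann$end_s - ann$start_s)
    hit <- c(hit, matches[[i]]$ann_matched)
  }
  c(detected = if (any(hit)) mean(lens[hit]) else NA_real_,
    missed = if (any(!hit)) mean(lens[!hit]) else NA_real_)
}
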