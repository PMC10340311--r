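#' Event types recognized by the pipeline
#' @export
SDB_TYPES <- c("hypopnea", "obstructive", "central", "mixed")

#' Sleep stage labels (30-s epochs)
#' @export
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Typed list of sleep-disordered-breathing events
#'
#' Intervals are in seconds from recording start, half-open `[start, end)`,
#' sorted by start, pairwise non-overlapping, each at least `min_duration`
#' seconds long. Detected (untyped) events use `type = NA`.
#'
#' @param start_s,end_s numeric vectors of interval edges in seconds.
#' @param type character vector of event types in [SDB_TYPES], or `NA` for
#'   untyped detections.
#' @param min_duration minimum accepted duration in seconds; set 0 to disable
#'   (detections carry no minimum).
#' @return a `data.frame` of class `event_list` with columns
#'   `start_s`, `end_s`, `type`.
#' @export
event_list <- function(start_s = numeric(), end_s = numeric(),
                       type = NA_character_, min_duration = 0) {
  n <- length(start_s)
  if (length(end_s) != n) stop("event_list: start_s/end_s length mismatch")
  type <- rep_len(as.character(type), max(n, 1L))[seq_len(n)]
  if (n > 0L) {
    if (any(!is.na(type) & !(type %in% SDB_TYPES))) {
      bad <- which(!is.na(type) & !(type %in% SDB_TYPES))[1]
      stop(sprintf("event_list: unknown event type '%s' (row %d)", type[bad], bad))
    }
    if (any(end_s <= start_s)) stop("event_list: require start_s < end_s")
    o <- order(start_s, end_s)
    start_s <- start_s[o]; end_s <- end_s[o]; type <- type[o]
    if (n > 1L && any(start_s[-1] < end_s[-n])) {
      stop("event_list: events overlap")
    }
    if (min_duration > 0 && any(end_s - start_s < min_duration)) {
      stop(sprintf("event_list: event shorter than %g s", min_duration))
    }
  }
  structure(data.frame(start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s),
                       type = type, stringsAsFactors = FALSE),
            class = c("event_list", "data.frame"))
}

#' Number of seconds covered by events
#' @param ev an `event_list`.
#' @export
event_seconds <- function(ev) if (nrow(ev) == 0L) 0 else sum(ev$end_s - ev$start_s)

#' Per-30-s-epoch hypnogram
#'
#' @param stages character vector of per-epoch stages in [SLEEP_STAGES].
#' @param epoch_s epoch length in seconds (default 30).
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stages <- as.character(stages)
  if (length(stages) < 1L) stop("hypnogram: need at least one epoch")
  if (!all(stages %in% SLEEP_STAGES)) stop("hypnogram: unknown stage label")
  structure(list(stages = stages, epoch_s = epoch_s), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs, TST %.1f min\n",
              length(x$stages), x$epoch_s, total_sleep_time(x) / 60))
  invisible(x)
}

#' Total sleep time in seconds
#' @param hyp a `hypnogram`.
#' @export
total_sleep_time <- function(hyp) {
  sum(hyp$stages != "W") * hyp$epoch_s
}

#' Sleep stage at given times
#' @param hyp a `hypnogram`.
#' @param t_s times in seconds from recording start.
#' @return character vector of stages (`NA` beyond the hypnogram).
#' @export
stage_at <- function(hyp, t_s) {
  idx <- floor(t_s / hyp$epoch_s) + 1L
  out <- rep(NA_character_, length(t_s))
  ok <- idx >= 1L & idx <= length(hyp$stages)
  out[ok] <- hyp$stages[idx[ok]]
  out
}

#' Per-second sleep mask
#' @param hyp a `hypnogram`.
#' @param duration_s recording duration in seconds.
#' @return logical vector, one entry per second, TRUE during sleep.
#' @export
sleep_mask <- function(hyp, duration_s) {
  st <- stage_at(hyp, seq_len(duration_s) - 1L)
  !is.na(st) & st != "W"
}

#' Per-second categorical track (e.g., body position)
#'
#' @param labels character vector, one label per second of recording.
#' @param categories allowed categories.
#' @return object of class `categorical_track`.
#' @export
categorical_track <- function(labels,
                              categories = c("supine", "prone", "left", "right")) {
  labels <- as.character(labels)
  if (!all(labels %in% categories)) stop("categorical_track: unknown label")
  structure(list(labels = labels, categories = categories),
            class = "categorical_track")
}

#' @export
print.categorical_track <- function(x, ...) {
  cat(sprintf("<categorical_track> %d s, categories: %s\n",
              length(x$labels), paste(x$categories, collapse = ", ")))
  invisible(x)
}
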