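#' @useDynLib sdbreath, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Minimal EDF (European Data Format) writer/reader: 16-bit samples, 1-second
# data records. No EDF package exists in this R stack, so the format is
# implemented directly; it is validated by round-trip tests.
# ---------------------------------------------------------------------------

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write sampled signals to an EDF file
#'
#' 16-bit EDF with 1-second data records; channel sampling rates must be
#' whole numbers. The final partial record is zero-padded.
#'
#' @param path output file path.
#' @param signals named list of `sampled_signal` (names become channel
#'   labels).
#' @param patient_id,recording_id header strings.
#' @return `path` invisibly.
#' @export
write_edf <- function(path, signals, patient_id = "X", recording_id = "synthetic") {
  stopifnot(length(signals) >= 1, !is.null(names(signals)))
  fs <- vapply(signals, function(s) s$fs, 0.0)
  if (any(fs != round(fs))) stop("write_edf: sampling rates must be integer Hz")
  n_rec <- max(vapply(signals, function(s) ceiling(length(s$values) / s$fs), 0))
  ns <- length(signals)
  pmin_ <- pmax_ <- numeric(ns)
  digmin <- -32768L; digmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wc <- function(x, width) writeChar(.edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wc("0", 8); wc(patient_id, 80); wc(recording_id, 80)
  wc("01.01.20", 8); wc("00.00.00", 8)
  wc(256 + 256 * ns, 8); wc("", 44); wc(n_rec, 8); wc("1", 8); wc(ns, 4)
  for (i in seq_len(ns)) {
    v <- signals[[i]]$values
    pmin_[i] <- min(v); pmax_[i] <- max(v)
    if (pmax_[i] <= pmin_[i]) pmax_[i] <- pmin_[i] + 1
  }
  for (nm in names(signals)) wc(nm, 16)
  for (i in seq_len(ns)) wc("synthetic", 80)
  for (i in seq_len(ns)) wc("au", 8)
  for (i in seq_len(ns)) wc(format(pmin_[i], digits = 8), 8)
  for (i in seq_len(ns)) wc(format(pmax_[i], digits = 8), 8)
  for (i in seq_len(ns)) wc(digmin, 8)
  for (i in seq_len(ns)) wc(digmax, 8)
  for (i in seq_len(ns)) wc("", 80)
  for (i in seq_len(ns)) wc(round(fs[i]), 8)
  for (i in seq_len(ns)) wc("", 32)
  # data records
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- signals[[i]]$values
    npad <- n_rec * fs[i] - length(v)
    if (npad > 0) v <- c(v, rep(0, npad))
    d <- round((v - pmin_[i]) / (pmax_[i] - pmin_[i]) * (digmax - digmin) + digmin)
    dig[[i]] <- as.integer(pmin(pmax(d, digmin), digmax))
  }
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * fs[i] + 1):(r * fs[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param labels optional channel labels to select (default: all).
#' @return named list of `sampled_signal`.
#' @export
read_edf <- function(path, labels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rc <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rc(8); rc(80); rc(80); rc(8); rc(8); rc(8); rc(44)
  n_rec <- as.integer(rc(8)); rec_dur <- as.numeric(rc(8)); ns <- as.integer(rc(4))
  lab <- vapply(seq_len(ns), function(i) rc(16), "")
  for (i in seq_len(ns)) rc(80)
  for (i in seq_len(ns)) rc(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rc(8)), 0.0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rc(8)), 0.0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rc(8)), 0.0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rc(8)), 0.0)
  for (i in seq_len(ns)) rc(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rc(8)), 0L)
  for (i in seq_len(ns)) rc(32)
  raw_ <- lapply(seq_len(ns), function(i) integer(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw_[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                signed = TRUE)
    }
  }
  out <- lapply(seq_len(ns), function(i) {
    v <- (raw_[[i]] - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
    sampled_signal(v, spr[i] / rec_dur)
  })
  names(out) <- lab
  if (!is.null(labels)) {
    missing_ <- setdiff(labels, lab)
    if (length(missing_)) {
      stop("read_edf: missing channel label(s): ", paste(missing_, collapse = ", "))
    }
    out <- out[labels]
  }
  out
}

# --- CSV / JSON annotation formats -----------------------------------------

#' Write events to CSV (columns start_s, end_s, type)
#' @param events an `event_list`.
#' @param path output path.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(start_s = sprintf("%.17g", events$start_s),
                   end_s = sprintf("%.17g", events$end_s),
                   type = events$type, stringsAsFactors = FALSE)
  if (nrow(events) == 0L) df <- df[0, ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read events from CSV with row-level validation
#' @param path CSV with columns `start_s`, `end_s`, `type`.
#' @param min_duration minimum event duration (default 0; annotations from
#'   the generator satisfy 10 s by construction).
#' @return an `event_list`.
#' @export
read_events_csv <- function(path, min_duration = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("start_s", "end_s", "type")
  if (!all(req %in% names(df))) stop("read_events_csv: malformed header")
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      if (!is.finite(df$start_s[i]) || !is.finite(df$end_s[i]) ||
          df$end_s[i] <= df$start_s[i]) {
        stop(sprintf("read_events_csv: invalid interval at row %d", i))
      }
      if (!df$type[i] %in% SDB_TYPES) {
        stop(sprintf("read_events_csv: unknown event type '%s' at row %d",
                     df$type[i], i))
      }
    }
  }
  event_list(df$start_s, df$end_s, df$type, min_duration = min_duration)
}

#' Write a hypnogram to CSV (columns epoch, stage)
#' @param hyp a `hypnogram`.
#' @param path output path.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  utils::write.csv(data.frame(epoch = seq_along(hyp$stages), stage = hyp$stages),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#' @param path CSV with columns `epoch`, `stage`.
#' @param epoch_s epoch length (default 30 s).
#' @export
read_hypnogram_csv <- function(path, epoch_s = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch", "stage") %in% names(df))) {
    stop("read_hypnogram_csv: malformed header")
  }
  hypnogram(df$stage[order(df$epoch)], epoch_s)
}

#' Write a subject record to disk
#'
#' EDF for the signals (channels `ECG`, `Effort`), CSVs for events,
#' hypnogram, position and beat times, JSON for demographics and the lights
#' window.
#'
#' @param rec a `subject_record`.
#' @param dir output directory (created if needed).
#' @return named list of file paths invisibly.
#' @export
write_record <- function(rec, dir) {
  stopifnot(inherits(rec, "subject_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, rec$id)
  paths <- list(
    edf = paste0(base, ".edf"),
    events = paste0(base, "_events.csv"),
    hypnogram = paste0(base, "_hypnogram.csv"),
    position = paste0(base, "_position.csv"),
    beats = paste0(base, "_beats.csv"),
    meta = paste0(base, "_meta.json"))
  write_edf(paths$edf, list(ECG = rec$ecg, Effort = rec$effort),
            patient_id = rec$id)
  write_events_csv(rec$events, paths$events)
  write_hypnogram_csv(rec$hypnogram, paths$hypnogram)
  utils::write.csv(data.frame(second = seq_along(rec$position$labels) - 1L,
                              position = rec$position$labels),
                   paths$position, row.names = FALSE)
  utils::write.csv(data.frame(time_s = rec$beat_times), paths$beats,
                   row.names = FALSE)
  meta <- list(id = rec$id, age = rec$age, bmi = rec$bmi, sex = rec$sex,
               severity = rec$severity, lights_off_s = rec$lights_off_s,
               lights_on_s = rec$lights_on_s, duration_s = rec$duration_s,
               reference_ahi = rec$reference_ahi, seed = rec$seed)
  jsonlite::write_json(meta, paths$meta, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a subject record from disk
#'
#' Inverse of [write_record()]; channel rates come from the EDF header and
#' the reference AHI is recomputed from the annotations and hypnogram.
#'
#' @param edf_path EDF with channels `ECG` and `Effort`.
#' @param events_path,hypnogram_path,position_path,beats_path,meta_path
#'   annotation CSV/JSON paths.
#' @return a `subject_record`.
#' @export
read_record <- function(edf_path, events_path, hypnogram_path,
                        position_path = NULL, beats_path = NULL,
                        meta_path = NULL) {
  sigs <- read_edf(edf_path, labels = c("ECG", "Effort"))
  events <- read_events_csv(events_path)
  hyp <- read_hypnogram_csv(hypnogram_path)
  meta <- if (!is.null(meta_path)) jsonlite::read_json(meta_path) else list()
  duration_s <- meta$duration_s %||% signal_duration(sigs$ECG)
  position <- if (!is.null(position_path)) {
    df <- utils::read.csv(position_path, stringsAsFactors = FALSE)
    categorical_track(df$position[order(df$second)])
  } else categorical_track(rep("supine", duration_s))
  beat_times <- if (!is.null(beats_path)) {
    utils::read.csv(beats_path)$time_s
  } else numeric(0)
  tst_h <- total_sleep_time(hyp) / 3600
  rec <- structure(list(
    id = meta$id %||% "unknown", age = meta$age %||% NA_real_,
    bmi = meta$bmi %||% NA_real_, sex = meta$sex %||% NA_character_,
    severity = meta$severity %||% NA_character_,
    target_ahi = NA_real_,
    ecg = sigs$ECG, effort = sigs$Effort, beat_times = beat_times,
    events = events, hypnogram = hyp, position = position,
    lights_off_s = meta$lights_off_s %||% 0,
    lights_on_s = meta$lights_on_s %||% duration_s,
    reference_ahi = if (tst_h > 0) nrow(events) / tst_h else NA_real_,
    duration_s = duration_s, seed = meta$seed %||% NA_integer_),
    class = "subject_record")
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default pipeline configuration
#'
#' All knobs of the end-to-end experiment in one JSON-serializable list:
#' cohort simulation, preprocessing, model/training, evaluation (matching
#' rule, threshold grid, NBL zones) and the root seed.
#'
#' @param n_subjects,duration_s cohort size and night length.
#' @param severity_mix per-class subject counts.
#' @param gru_width,dense_width,max_epochs,patience,batch_size model and
#'   training scale.
#' @param pairings input pairings to train (`"rr_re"`, `"rr_edr"`).
#' @param seed root seed; all stage seeds derive from it.
#' @param out_dir experiment directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 20,
                            duration_s = 7200,
                            severity_mix = c(normal = 5, mild = 5,
                                             moderate = 5, severe = 5),
                            gru_width = 16L, dense_width = 64L,
                            max_epochs = 30L, patience = 5L,
                            batch_size = 128L,
                            pairings = c("rr_re", "rr_edr"),
                            seed = 1L, out_dir = tempfile("sdb_run_")) {
  structure(list(n_subjects = n_subjects, duration_s = duration_s,
                 severity_mix = as.list(severity_mix),
                 gru_width = gru_width, dense_width = dense_width,
                 max_epochs = max_epochs, patience = patience,
                 batch_size = batch_size, pairings = pairings,
                 nbl_zones = as.list(NBL_ZONES_DEFAULT),
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (lossless JSON round-trip)
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$severity_mix <- as.list(cfg$severity_mix)
  cfg$nbl_zones <- as.list(cfg$nbl_zones)
  structure(cfg, class = "pipeline_config")
}
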