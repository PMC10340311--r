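#' Predict a whole night for one subject
#'
#' Segments the preprocessed channels under the requested pairing, runs the
#' model, stitches the central 3-minute intervals and masks wake.
#'
#' @param model a trained `sdb_model`.
#' @param prep output of [preprocess_record()].
#' @param rec the `subject_record`.
#' @param pairing `"rr_re"` or `"rr_edr"`.
#' @return a wake-masked `night_prediction`.
#' @export
predict_night <- function(model, prep, rec, pairing = "rr_re") {
  segs <- segments_for_pairing(prep, rec, pairing)
  if (length(segs) == 0L) stop("predict_night: no segments for subject ", rec$id)
  probs <- predict_segments(model, segs)
  starts <- vapply(segs, `[[`, 0.0, "start_s")
  pred <- stitch_predictions(probs, starts, duration_s = rec$duration_s,
                             subject_id = rec$id)
  mask_wake(pred, rec$hypnogram)
}

.log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

# Evaluate one pairing on a set of subjects at a fixed threshold.
.evaluate_subjects <- function(model, cohort, preps, ids, pairing, threshold) {
  matches_strict <- list(); matches_olsen <- list(); ann_clipped <- list()
  tracks_stage <- list(); tracks_pos <- list()
  est_ahi <- numeric(0); ref_ahi <- numeric(0)
  age <- numeric(0); bmi <- numeric(0)
  for (id in ids) {
    i <- which(vapply(cohort, `[[`, "", "id") == id)
    rec <- cohort[[i]]
    pred <- predict_night(model, preps[[i]], rec, pairing)
    det <- binarize_events(pred, threshold)
    ann <- clip_events_to_scored(rec$events, pred)
    matches_strict[[id]] <- match_events_strict(det, ann)
    matches_olsen[[id]] <- match_events_olsen(det, ann)
    ann_clipped[[id]] <- ann
    tracks_stage[[id]] <- rec$hypnogram
    tracks_pos[[id]] <- rec$position
    est_ahi <- c(est_ahi, compute_ahi(nrow(det), rec$hypnogram))
    ref_ahi <- c(ref_ahi, rec$reference_ahi)
    age <- c(age, rec$age); bmi <- c(bmi, rec$bmi)
  }
  list(strict = detection_metrics(matches_strict),
       olsen = detection_metrics(matches_olsen),
       by_type = detection_rate_by_type(matches_strict, ann_clipped),
       by_stage = stratified_detection_rate(matches_strict, ann_clipped,
                                            tracks_stage),
       by_position = stratified_detection_rate(matches_strict, ann_clipped,
                                               tracks_pos),
       event_length = event_length_summary(matches_strict, ann_clipped),
       matches_strict = matches_strict, matches_olsen = matches_olsen,
       est_ahi = est_ahi, ref_ahi = ref_ahi,
       covariates = data.frame(age = age, bmi = bmi))
}

# Flatten an evaluation into JSON-friendly numbers.
.summarize_eval <- function(ev, threshold) {
  ag <- agreement_report(ev$est_ahi, ev$ref_ahi, ev$covariates)
  list(threshold = threshold,
       strict = list(pooled = as.list(ev$strict$pooled),
                     mean = as.list(ev$strict$mean),
                     sd = as.list(ev$strict$sd)),
       olsen = list(pooled = as.list(ev$olsen$pooled)),
       detection_rate_by_type = as.list(ev$by_type),
       detection_rate_by_stage = as.list(ev$by_stage),
       detection_rate_by_position = as.list(ev$by_position),
       event_length = as.list(ev$event_length),
       agreement = list(
         bias = ag$bland_altman$bias,
         loa_half_width = ag$bland_altman$loa_half_width,
         sd_diff = ag$bland_altman$sd_diff,
         spearman_r = ag$spearman$r, spearman_p = ag$spearman$p,
         icc = ag$icc$icc, icc_ci = ag$icc$ci,
         accuracy = ag$severity$accuracy, kappa = ag$severity$kappa,
         accuracy_nbl = ag$severity$accuracy_nbl,
         kappa_nbl = ag$severity$kappa_nbl,
         nbl_zones = as.list(ag$severity$zones)))
}

#' Run the full experiment pipeline
#'
#' simulate -> preprocess -> stratified split -> train (each input pairing)
#' -> threshold selection on validation -> test-set evaluation under the
#' strict and any-overlap rules -> AHI agreement report. All artifacts, the
#' resolved configuration and a log (with seeds and package version) are
#' persisted in `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return invisibly, a list with the per-pairing reports and artifact
#'   paths.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  .log_line(log_path, "pipeline start: seed=", config$seed,
            " sdbreath=", as.character(utils::packageVersion("sdbreath")))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  simcfg <- sim_config(duration_s = config$duration_s, seed = config$seed)
  cohort <- run_stage("simulate", generate_cohort(
    config$n_subjects, unlist(config$severity_mix), seed = config$seed,
    config = simcfg))
  .log_line(log_path, "simulated ", length(cohort), " subjects")

  preps <- run_stage("preprocess", lapply(cohort, preprocess_record))
  .log_line(log_path, "preprocessed")

  sev <- stats::setNames(vapply(cohort, `[[`, "", "severity"),
                         vapply(cohort, `[[`, "", "id"))
  split <- run_stage("split", stratified_split(sev, seed = config$seed + 1L))
  .log_line(log_path, "split: ", paste(names(table(split)), table(split),
                                       collapse = " ", sep = "="))

  mcfg <- model_config(gru_width = config$gru_width,
                       dense_width = config$dense_width)
  reports <- list()
  for (pi in seq_along(config$pairings)) {
    pairing <- config$pairings[pi]
    seg_of <- function(ids) {
      unlist(lapply(ids, function(id) {
        i <- which(names(sev) == id)
        segments_for_pairing(preps[[i]], cohort[[i]], pairing)
      }), recursive = FALSE)
    }
    train_ids <- names(split)[split == "train"]
    val_ids <- names(split)[split == "validation"]
    test_ids <- names(split)[split == "test"]
    model <- run_stage("train", {
      m <- build_model(mcfg, seed = config$seed + 100L + pi)
      tcfg <- train_config(batch_size = config$batch_size,
                           patience = config$patience,
                           max_epochs = config$max_epochs,
                           seed = config$seed + 200L + pi)
      train_model(m, seg_of(train_ids), seg_of(val_ids), tcfg,
                  verbose = verbose)
    })
    .log_line(log_path, pairing, ": trained ", nrow(model$history), " epochs")
    thr <- run_stage("threshold", {
      nights <- lapply(val_ids, function(id) {
        i <- which(names(sev) == id)
        list(pred = predict_night(model, preps[[i]], cohort[[i]], pairing),
             annotated = cohort[[i]]$events)
      })
      select_threshold(nights)
    })
    .log_line(log_path, pairing, ": threshold ", thr$threshold)
    ev <- run_stage("evaluate", .evaluate_subjects(
      model, cohort, preps, test_ids, pairing, thr$threshold))
    reports[[pairing]] <- .summarize_eval(ev, thr$threshold)
    .log_line(log_path, sprintf("%s: pooled strict F1 %.3f",
                                pairing, ev$strict$pooled["f1"]))
    saveRDS(model, file.path(out_dir, paste0("model_", pairing, ".rds")))
    utils::write.csv(model$history,
                     file.path(out_dir, paste0("training_", pairing, ".csv")),
                     row.names = FALSE)
    per <- ev$strict$per_subject
    per$subject <- test_ids
    utils::write.csv(per, file.path(out_dir, paste0("detections_", pairing, ".csv")),
                     row.names = FALSE)
    # plot-ready Bland-Altman / scatter table
    utils::write.csv(cbind(data.frame(subject = test_ids,
                                      ahi_est = ev$est_ahi,
                                      ahi_ref = ev$ref_ahi),
                           ev$covariates),
                     file.path(out_dir, paste0("ahi_pairs_", pairing, ".csv")),
                     row.names = FALSE)
  }
  report <- list(config = unclass(config), pairings = reports)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  write_config(config, file.path(out_dir, "config.json"))
  .log_line(log_path, "pipeline done")
  invisible(list(report = report, out_dir = out_dir,
                 report_path = file.path(out_dir, "report.json")))
}
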