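test_that("stitch_predictions keeps central intervals on the 180-s grid", {
  probs <- matrix(runif(2 * 300), 2, 300)
  np <- stitch_predictions(probs, c(0, 180))
  expect_length(np$probs, 480)
  expect_equal(which(np$scored) - 1L, 60:419)        # covered span [60, 420)
  expect_true(all(np$probs[1:60] == 0))
  expect_equal(np$probs[61], probs[1, 61])
  expect_equal(np$probs[241], probs[2, 61])
  # single segment scores exactly 180 s
  np1 <- stitch_predictions(matrix(runif(300), 1, 300), 0)
  expect_equal(sum(np1$scored), 180)
  # tiling: scored seconds = 180 x segments
  np3 <- stitch_predictions(matrix(runif(3 * 300), 3, 300), c(0, 180, 360))
  expect_equal(sum(np3$scored), 540)
  expect_error(stitch_predictions(probs, c(0, 90)), "grid")
})

test_that("mask_wake zeroes exactly the wake epochs", {
  hyp <- hypnogram(c("W", "N2", "W", "N2"))
  pred <- night_prediction(rep(0.8, 120))
  mk <- mask_wake(pred, hyp)
  expect_true(all(mk$probs[c(1:30, 61:90)] == 0))
  expect_true(all(mk$probs[c(31:60, 91:120)] == 0.8))
  # all-sleep hypnogram is the identity
  hs <- hypnogram(rep("N2", 4))
  expect_equal(mask_wake(pred, hs)$probs, pred$probs)
  # all-wake zeroes everything
  hw <- hypnogram(rep("W", 4))
  expect_true(all(mask_wake(pred, hw)$probs == 0))
})

test_that("binarize_events applies the strict-inequality run rule", {
  pred <- night_prediction(c(0, 0, 0.9, 0.9, 0, 0.8))
  ev <- binarize_events(pred, 0.5)
  expect_equal(ev$start_s, c(2, 5))
  expect_equal(ev$end_s, c(4, 6))
  expect_equal(nrow(binarize_events(pred, 0.95)), 0L)
  # threshold equal to the maximum: strictly-greater rule leaves nothing
  expect_equal(nrow(binarize_events(night_prediction(rep(0.9, 10)), 0.9)), 0L)
  # unscored seconds carry probability 0 and cannot form events
  expect_error(night_prediction(c(0, 0.9, 0.9, 0),
                                scored = c(TRUE, FALSE, FALSE, TRUE)),
               "unscored")
  p2 <- night_prediction(c(0, 0.9, 0, 0.9), scored = c(TRUE, TRUE, FALSE, TRUE))
  ev2 <- binarize_events(p2, 0.5)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$end_s - ev2$start_s, c(1, 1))
})

test_that("matchers reproduce the published counting scenarios", {
  # second overlapping detection: FP under strict, TP under any-overlap
  ann <- event_list(0, 30, "hypopnea")
  det <- event_list(c(0, 20), c(10, 30), NA_character_)
  ms <- match_events_strict(det, ann)
  expect_equal(c(ms$tp, ms$fp, ms$fn), c(1, 1, 0))
  mo <- match_events_olsen(det, ann)
  expect_equal(c(mo$tp, mo$fp, mo$fn), c(2, 0, 0))
  # one detection spanning two annotations: second annotation FN under
  # strict, detected under any-overlap
  ann2 <- event_list(c(0, 20), c(10, 30), c("central", "central"))
  det2 <- event_list(5, 25, NA_character_)
  ms2 <- match_events_strict(det2, ann2)
  expect_equal(c(ms2$tp, ms2$fp, ms2$fn), c(1, 0, 1))
  mo2 <- match_events_olsen(det2, ann2)
  expect_equal(c(mo2$tp, mo2$fp, mo2$fn), c(1, 0, 0))
  # degenerate inputs
  m0 <- match_events_strict(event_list(), ann)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0, 0, 1))
  m1 <- match_events_olsen(event_list(0, 5, NA_character_), event_list())
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(0, 1, 0))
})

test_that("matchers agree with brute-force oracles on random instances", {
  set.seed(99)
  for (i in 1:200) {
    det <- random_event_set()
    ann <- random_event_set()
    ms <- match_events_strict(det, ann)
    os <- oracle_match_strict(det, ann)
    expect_equal(c(ms$tp, ms$fp, ms$fn), c(os$tp, os$fp, os$fn))
    mo <- match_events_olsen(det, ann)
    oo <- oracle_match_olsen(det, ann)
    expect_equal(c(mo$tp, mo$fp, mo$fn), c(oo$tp, oo$fp, oo$fn))
    # bookkeeping invariants
    expect_equal(ms$tp + ms$fp, nrow(det))
    expect_equal(ms$tp + ms$fn, nrow(ann))
    expect_lte(ms$tp, mo$tp)
  }
})

test_that("select_threshold equals the exhaustive grid argmax", {
  ev <- event_list(c(100, 300, 500), c(130, 340, 520),
                   c("hypopnea", "central", "obstructive"))
  night <- list(pred = synthetic_night(ev, 720), annotated = ev)
  sel <- select_threshold(list(night))
  expect_length(sel$grid, 249)
  expect_equal(min(sel$grid), 0.004)
  expect_equal(max(sel$grid), 0.996)
  # under the strictly-greater rule every grid point in [0.1, 0.9) attains
  # F1 = 1 (at exactly 0.1 the outside-event seconds are excluded too);
  # ties resolve to the smallest such point
  expect_true(all(sel$f1[sel$grid >= 0.1 & sel$grid < 0.9] == 1))
  expect_equal(sel$threshold, min(sel$grid[sel$f1 == 1]))
  expect_equal(sel$threshold, 0.004 * 25)
  expect_equal(max(sel$f1), 1)
  # oracle identity: recompute F1 at every grid point independently
  f1_oracle <- vapply(sel$grid, function(tau) {
    det <- binarize_events(night$pred, tau)
    m <- oracle_match_strict(det, ev)
    if (m$tp == 0) return(0)
    p <- m$tp / (m$tp + m$fp); s <- m$tp / (m$tp + m$fn)
    2 * p * s / (p + s)
  }, 0.0)
  expect_equal(sel$f1, f1_oracle)
  # single-point grid
  expect_equal(select_threshold(list(night), grid = 0.5)$threshold, 0.5)
  # raising the threshold never increases detected seconds
  secs <- vapply(sel$grid, function(tau) {
    event_seconds(binarize_events(night$pred, tau))
  }, 0.0)
  expect_true(all(diff(secs) <= 0))
})

test_that("detection_metrics computes per-subject and pooled ratios", {
  m1 <- structure(list(tp = 77, fp = 41, fn = 23,
                       ann_matched = logical(0), det_matched = logical(0)),
                  class = "match_counts")
  dm <- detection_metrics(list(m1))
  expect_equal(unname(dm$pooled["sensitivity"]), 0.77)
  expect_equal(unname(dm$pooled["precision"]), 77 / 118, tolerance = 1e-6)
  expect_equal(unname(dm$pooled["f1"]),
               2 * 0.77 * (77 / 118) / (0.77 + 77 / 118), tolerance = 1e-6)
  # pooled differs from mean-of-subjects on a constructed two-night case
  m2 <- structure(list(tp = 1, fp = 0, fn = 9), class = "match_counts")
  m3 <- structure(list(tp = 90, fp = 10, fn = 0), class = "match_counts")
  dm2 <- detection_metrics(list(m2, m3))
  expect_false(isTRUE(all.equal(unname(dm2$pooled["sensitivity"]),
                                unname(dm2$mean["sensitivity"]))))
  # perfect detection
  mp <- structure(list(tp = 5, fp = 0, fn = 0), class = "match_counts")
  expect_true(all(detection_metrics(list(mp))$pooled == 1))
})

test_that("per-type and stratified detection rates partition the events", {
  ann <- list(event_list(c(0, 50, 100), c(20, 70, 120),
                         c("hypopnea", "central", "obstructive")))
  mm <- list(structure(list(tp = 2, fp = 0, fn = 1,
                            ann_matched = c(FALSE, TRUE, TRUE)),
                       class = "match_counts"))
  rates <- detection_rate_by_type(mm, ann)
  expect_equal(rates[["hypopnea"]], 0)
  expect_equal(rates[["central"]], 1)
  # type counts conserved
  expect_equal(length(mm[[1]]$ann_matched), nrow(ann[[1]]))
  hyp <- hypnogram(rep("N2", 5))
  sr <- stratified_detection_rate(mm, ann, list(hyp))
  expect_named(sr, "N2")
  expect_equal(unname(sr), 2 / 3)
  pos <- categorical_track(rep("supine", 150))
  sp <- stratified_detection_rate(mm, ann, list(pos))
  expect_named(sp, "supine")
  lens <- event_length_summary(mm, ann)
  expect_equal(unname(lens["detected"]), 20)
  expect_equal(unname(lens["missed"]), 20)
  # all detected -> missed mean absent
  mm2 <- list(structure(list(tp = 3, fp = 0, fn = 0,
                             ann_matched = rep(TRUE, 3)),
                        class = "match_counts"))
  expect_true(is.na(event_length_summary(mm2, ann)["missed"]))
})

test_that("clip_events_to_scored drops uncovered annotation fragments", {
  pred <- night_prediction(c(rep(0, 60), runif(180), rep(0, 60)),
                           scored = rep(c(FALSE, TRUE, FALSE), c(60, 180, 60)))
  ev <- event_list(c(10, 100, 250), c(30, 130, 290), rep("central", 3))
  cl <- clip_events_to_scored(ev, pred)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start_s, 100)
})
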