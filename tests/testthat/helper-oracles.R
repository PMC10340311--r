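# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use different code paths (plain double loops, aov(),
# rank formulas) from the package implementations they check.

# Brute-force strict matcher: scan annotated events in time order; each takes
# the earliest-starting overlapping unmatched detection. Plain double loop.
oracle_match_strict <- function(detected, annotated) {
  nd <- nrow(detected); na <- nrow(annotated)
  used <- rep(FALSE, nd)
  tp <- 0L
  for (i in seq_len(na)) {
    cand <- c()
    for (j in seq_len(nd)) {
      if (!used[j] &&
          detected$start_s[j] < annotated$end_s[i] &&
          detected$end_s[j] > annotated$start_s[i]) {
        cand <- c(cand, j)
      }
    }
    if (length(cand) > 0) {
      j <- cand[which.min(detected$start_s[cand])]
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nd - tp, fn = na - tp)
}

oracle_match_olsen <- function(detected, annotated) {
  nd <- nrow(detected); na <- nrow(annotated)
  ov <- function(j, i) detected$start_s[j] < annotated$end_s[i] &&
    detected$end_s[j] > annotated$start_s[i]
  tp <- 0L
  for (j in seq_len(nd)) {
    hit <- FALSE
    for (i in seq_len(na)) if (ov(j, i)) hit <- TRUE
    if (hit) tp <- tp + 1L
  }
  fn <- 0L
  for (i in seq_len(na)) {
    hit <- FALSE
    for (j in seq_len(nd)) if (ov(j, i)) hit <- TRUE
    if (!hit) fn <- fn + 1L
  }
  list(tp = tp, fp = nd - tp, fn = fn)
}

# Random sorted non-overlapping interval set on [0, span).
random_event_set <- function(n_max = 20, span = 1000) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  if (n == 0L) return(event_list())
  edges <- sort(runif(2 * n, 0, span))
  starts <- edges[seq(1, 2 * n, by = 2)]
  ends <- edges[seq(2, 2 * n, by = 2)]
  ok <- ends - starts > 0.5
  if (!any(ok)) return(event_list())
  event_list(starts[ok], ends[ok], NA_character_)
}

# ICC(2,1) oracle from two-way ANOVA mean squares via aov().
oracle_icc21 <- function(est, ref) {
  n <- length(est)
  d <- data.frame(y = c(ref, est),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# Spearman oracle from the rank formula with average ties.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Tiny synthetic subject used by several tests (fast: short night).
quick_subject <- function(seed = 11, duration_s = 1800, severity = "severe") {
  generate_subject(sim_config(duration_s = duration_s), seed = seed,
                   severity = severity)
}

# A night prediction with probabilities p_in inside events, p_out outside.
synthetic_night <- function(events, duration_s, p_in = 0.9, p_out = 0.1) {
  probs <- rep(p_out, duration_s)
  for (i in seq_len(nrow(events))) {
    sec <- floor(events$start_s[i]):(ceiling(events$end_s[i]) - 1)
    probs[sec + 1] <- p_in
  }
  night_prediction(probs)
}
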