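---
title: "Methods: cardiorespiratory SDB detection on synthetic nights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiorespiratory SDB detection on synthetic nights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Sleep-disordered breathing (SDB) shows up in two signals that are easy to
acquire outside the sleep laboratory: the heart rhythm (apneas drive a
cyclic bradycardia–tachycardia oscillation, and respiration modulates QRS
amplitudes) and thoracic respiratory effort (central apneas abolish it,
obstructive apneas leave it reduced but present, hypopneas attenuate it).
`sdbreath` implements a sequence-labeling detector over these signals: two
4 Hz input channels — the RR-interval series plus either respiratory effort
(RE) or ECG-derived respiration (EDR) — are cut into 5-minute windows and
mapped by a recurrent network to a per-second probability that the moment
belongs to an SDB event. Detected events are compared with annotations at
the event level, and per-night event counts divided by total sleep time give
the estimated apnea–hypopnea index (AHI), from which severity classes and
agreement statistics follow.

The network is deliberately conventional: two feature blocks of
[BiGRU, BiGRU, batch normalization, stride-2 max-pooling over time, ReLU,
dropout 0.5], then a dense-ReLU and a dense-sigmoid head. Two pooling
stages take 1200 input steps (4 Hz × 300 s) to 300 outputs (1 Hz); this
time-length ledger is asserted at build time. Training minimizes
per-timestep binary cross-entropy with sample weights 1 (label 0) and 10
(label 1), using Adam at learning rate 0.001, decoupled weight decay 1e-4,
batch size 128, early stopping with patience 20 on validation loss, and
restoration of the best-validation weights. Sigmoid output plus per-sample
weighting makes weighted BCE the only consistent loss choice. Because no
deep-learning framework exists in the target environment, the GRU
forward/backward passes are hand-implemented (RcppArmadillo) and verified
against finite differences to ~1e-6 relative error in the test suite.

## The synthetic world

Real polysomnography with event annotations cannot be shipped, so the
generator *is* a first-class, tested module, and its defaults are the
package's statement of what a plausible clinical night looks like:

- **Night structure**: 8-h recordings; a semi-Markov hypnogram over
  W/N1/N2/N3/REM with a 10-min sleep latency, brief awakenings, and wake at
  the edges; body-position bouts averaging 40 min.
- **Events**: planted only inside sleep, log-normal durations (median 22 s)
  clipped to [10, 120] s, at least 5 s apart; the type mix
  (hypopnea 0.83, obstructive 0.09, central 0.05, mixed 0.03) follows the
  event-count proportions reported for clinical cohorts of this kind. The
  event count is `round(AHI_target × TST_h)`, so the annotation-derived AHI
  recovers the target up to rounding — this is what makes severity classes
  recoverable by construction.
- **Cardiac channel**: ECG at 256 Hz built from Gaussian-template QRS
  complexes at integrated beat times (baseline 55–75 bpm, slow drift,
  respiratory sinus arrhythmia, a 10-bpm bradycardia-then-tachycardia
  excursion around each event, optional premature beats at 3/h); QRS
  amplitude is modulated ±20% by the instantaneous respiration value — the
  substrate EDR extraction relies on.
- **Effort channel**: 32 Hz quasi-sinusoid at 0.25 Hz with slow rate and
  amplitude drift; inside events the envelope scales by type (central 0.05,
  obstructive 0.4, hypopnea 0.5, mixed = central-then-obstructive halves,
  the clinical definition), with 1-s ramps and a 35% recovery overshoot
  decaying over ~8 s after each event.

What the generator does **not** emulate: realistic ECG morphology (P/T
waves, arrhythmias beyond isolated ectopy), electrode artifacts, SpO2 or
airflow, arousals, inter-subject variability of event signatures beyond the
configured ranges. A green end-to-end test therefore establishes that the
pipeline is wired correctly and can recover a *learnable* signature at the
stated signal-to-noise; it does not certify clinical performance, and the
package intentionally reports desk-scale results only as internal
consistency checks.

## Preprocessing choices

- R peaks: derivative–square–integrate energy transform, adaptive threshold
  at 25% of the 99th percentile, 250 ms refractory period, parabolic
  sub-sample refinement. (A tangent-intersection refinement exists in the
  literature; nothing downstream depends on sub-sample beat timing, so the
  parabolic fit suffices.)
- Ectopic rejection: a beat is invalid when its interval deviates more than
  30% (configurable) from the previous accepted interval — a symmetric
  restriction on heart-rate acceleration/deceleration. Gradual drifts pass.
- RR series: intervals between valid beats are attached to interval
  midpoints, linearly interpolated, and sampled at 4 Hz. Samples inside the
  *enclosing inter-beat span* of an invalid beat are set exactly to 0 — the
  model treats zeros as missing. (The span definition is a documented
  choice; a beat-centered window would be equally defensible.)
- EDR: each QRS (window ±60 ms) is delay-embedded (delay 20 ms) in 2-D and
  summarized by the area swept by the trajectory (shoelace formula), which
  grows monotonically with QRS amplitude; the per-beat series is
  interpolated to 4 Hz and linearly detrended. All parameters configurable.
- Effort: windowed-sinc anti-aliased resampling to 4 Hz (so components
  above the 2 Hz Nyquist are removed by construction), then a 4th-order
  Butterworth high-pass at 0.05 Hz applied forward–backward. Zero-phase
  filtering keeps event timing aligned with the annotations; the
  forward-backward pass starts from the edge value so constant inputs map
  exactly to zero.

## Dataset and evaluation semantics

- Windows: 300 s every 180 s (120 s overlap), anchored at lights-off,
  wholly inside the lights window; trailing partial windows dropped.
- Normalization: "soft" min–max maps the 5th/95th percentile to 0/1
  (percentiles by linear interpolation between order statistics, R type 7 —
  stated because it changes small-sample values). Outputs are *not*
  clipped: recovery overshoots carry signal. A constant channel maps to
  0.5 with a warning.
- Stitching: only the central 3 minutes of each window enter the night
  series; uncovered seconds are marked unscored, excluded from event
  formation, and annotations are clipped to the scored span before matching
  so uncovered seconds can neither credit nor penalize.
- Thresholding: maximal runs of seconds with probability **strictly**
  greater than the threshold; no minimum duration, no merging of close
  events. One consequence worth knowing: if out-of-event probabilities sit
  exactly at a grid value, that grid value itself already excludes them.
- Matching: the strict rule is a greedy one-to-one temporal matching —
  annotations scanned in time order, each credited to its earliest-starting
  overlapping unmatched detection. This reading reproduces both canonical
  counting vignettes (a second overlapping detection is a false positive; a
  single detection spanning two annotations leaves the second annotation a
  false negative) and is verified against a brute-force oracle on a
  thousand random instances. The any-overlap ("Olsen") rule is kept as an
  alternative for comparability.
- Threshold selection maximizes pooled strict-rule F1 over a fixed grid
  (0.004 to 0.996, step 0.004; 249 points) on validation nights; ties go to
  the smallest threshold.
- Undefined per-subject ratios (0/0) are excluded from mean ± SD summaries
  with a warning; pooled metrics come from summed counts.

## Agreement statistics

AHI uses total sleep time from the hypnogram (all non-wake epochs).
Bland–Altman reports bias and 1.96 × SD limits; both the SD and its 1.96
multiple are emitted because published limits are sometimes quoted either
way. Spearman correlations use average ranks and a two-sided t
approximation; an AHI < 30 subgroup is reported because a few severe
subjects dominate rank correlations otherwise. ICC is the two-way
random-effects, absolute-agreement, single-rater ICC(2,1) with a
Satterthwaite F-based 95% CI, checked against a variance-components oracle
to 1e-10. Severity classes use the canonical 5/15/30 thresholds; values
exactly on a boundary go to the **upper** class (the strict inequalities in
the usual definition leave boundaries unassigned; this choice is documented
and configurable). Near-boundary double-labeling (NBL) assigns a reference
AHI inside a zone around a boundary to both adjacent classes and counts the
estimate correct if it matches either; the original zone widths are not
published, so the default half-widths are 10% of each boundary (0.5, 1.5,
3.0 events/h), configurable and always echoed in reports. Kappa under NBL
is computed on the resolved assignments (twin-matched subjects counted in
the matching class).

## Numerical and engineering choices

- Batch-norm running statistics use momentum 0.9 (not the framework-typical
  0.99): desk-scale trainings take only tens of optimizer steps, and a 0.99
  average would still be dominated by its initialization at evaluation
  time.
- Kernel regularization is L2 at 1e-5 on recurrent and dense kernels;
  weight decay is decoupled (applied after the Adam step) — "Adam with
  weight decay" is ambiguous, so the decoupled reading is stated and
  configurable. Biases and batch-norm parameters are exempt from both.
- Initialization is variance-scaling (Glorot-uniform for GRU and output
  kernels, He-normal for the ReLU dense layer), a robust stand-in for
  unpublished schemes.
- Max-pooling acts on the time axis only; ties break toward the earlier
  timestep, making inference exactly reproducible.
- The BLAS is pinned to one thread at package load: the recurrent GEMMs are
  small, thread-pool synchronization dominates otherwise, and
  single-threading makes training bit-reproducible on one CPU.
- All randomness flows from explicit seeds: cohort seeds spawn per-subject
  seeds; the pipeline derives per-stage seeds from its root seed, so
  partial reruns are reproducible.

## Desk scale versus stated scale

Generator defaults describe full 8-h nights at clinical sampling rates.
The test suite and the pipeline examples run *scaled-down* worlds — 1-h
nights, the reduced model preset (GRU width 16, dense 64), 12 or fewer
epochs, 20 subjects — purely to fit a single-CPU time budget; this is a
computational concession, not a claim about the stated world. At that scale
the RR + RE and RR + EDR pairings both solve the synthetic task (pooled
strict F1 ≈ 0.7) and their ordering is within noise: the synthetic EDR
substrate is a clean amplitude modulation, so EDR is not degraded relative
to effort the way it is in real recordings. The end-to-end acceptance check
therefore asserts RR + RE performance absolutely and the pairing comparison
only directionally with a soft margin.

## Known limitations

- The hand-rolled EDF writer/reader covers the 16-bit, 1-s-record subset it
  writes; it is not a general EDF+ implementation.
- The detector consumes reference hypnograms for wake masking and AHI
  denominators; no sleep–wake classifier is included.
- Epoch-based (per-minute) scoring common in older apnea-screening
  literature is intentionally out of scope; all scoring is event-based.
- Severity recovery on synthetic cohorts is exact by construction when
  targets sit well inside class bands; it says nothing about behavior at
  class boundaries with real scorer noise (that is what NBL is for).
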