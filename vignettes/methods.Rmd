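---
title: "Reduced-channel EEG seizure detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-channel EEG seizure detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the processing
model and its assumptions, the tunable parameters with their defaults and
units, what the synthetic-data generator does and does not emulate, the
numerical conventions, and the places where the design was genuinely open
and a choice had to be made.

## The problem and the signal

Four single-channel wearable sensors record scalp EEG below the hairline at
the approximate F7/F8 (forehead: `LF`, `RF`) and T5/T6 (behind-ear: `LE`,
`RE`) positions. The device envelope is 512 Hz sampling, a 10-bit ADC over
±175 µV full scale, and a 0.8–92 Hz amplifier passband. Review and
detection operate on a 10-channel montage: the four referential channels
plus the six pairwise differentials in the fixed lexicographic order
`LF-RF, LF-LE, LF-RE, RF-LE, RF-RE, LE-RE`. The source montage description
does not enumerate the pair order; fixing it lexicographically makes file
outputs and tests deterministic. Alignment between sensors uses the EDF
start timestamps, trimming to the common temporal overlap; hardware-level
time synchronization is out of scope. All times are seconds from a cohort
epoch and all intervals are half-open `[start, stop)`.

EDF files are written as classic EDF (16-bit samples over the ±175 µV
physical range) rather than EDF+ with an annotations stream: every EDF+
reader accepts classic EDF, annotations travel separately as CSV, and the
container then stays trivially verifiable. The sensor's 10-bit grid is
applied by the simulator, not the container.

## Segment scoring and features

The montage is cut into contiguous, non-overlapping 2-s windows (the
source describes 2-s segmentation and never mentions overlap; a trailing
partial window is dropped). Windows overlapping a known seizure by any
amount are `ictal` — mirroring the any-overlap philosophy used at event
level — windows within 15 min (900 s) before or after a seizure are
`near_ictal`, and everything else is `non_ictal`. Near-ictal windows are
excluded from training because peri-ictal EEG confounds a binary
classifier; they are still scored at detection time.

The feature families are named in the source only by example ("variance",
"power in delta band", "wavelet convolutions", "entropy"), so the concrete
list is this package's choice of standard seizure-detection features, one
block per named domain, per channel:

* time: variance, line length, RMS;
* frequency: absolute and relative band power in δ (0.8–4), θ (4–8),
  α (8–13), β (13–30), γ (30–70 Hz), from a Hann-windowed periodogram
  (bands are clipped at the Nyquist frequency when a reduced sampling rate
  is used);
* time-frequency: Haar discrete-wavelet detail energy at 6 levels;
* complexity: spectral entropy (normalized to [0, 1] over the in-band
  periodogram) and sample entropy (embedding m = 2, tolerance 0.2·SD).

That is 21 base features × 10 channels. Because seizures evolve, each
feature is augmented with an exponentially weighted history
`h_t = α_h·h_{t−1} + (1 − α_h)·f_t`, `h_1 = f_1`, with `α_h = 0.8`
(≈ 10-segment / 20-s memory). The source says only "weighted average of
prior segments"; a first-order exponential average is the simplest
operator with that property and one tunable horizon. "Cross-channel
correlations for all features" is ambiguous; it is implemented as (a) the
across-channel mean, SD, max and min of each base feature over the 10
channels and (b) the six zero-lag Pearson correlations of the broadband
sensor-pair signals per window — bounded dimensionality that captures
inter-sensor synchrony. The final vector has
`21×10×2 + 21×4 + 6 = 510` features. Whether the source computed features
on all 10 channels or only the 4 sensors is not stated; all 10 are used
(the montage is the declared algorithm input).

Numerical conventions: a flat (zero-variance) window has zero entropies by
convention, not an error; a zero-variance channel contributes pairwise
correlation 0; relative band powers of an empty spectrum are 0. Sample
entropy — quadratic in window length — is computed on an 8:1 decimated
window (64 Hz effective, still > 4× the dominant ictal frequencies); at
full rate it alone would dominate the cohort-scale runtime.

## Detector

For each subject, a training pool combines all other subjects' windows
(leave-one-subject-out): every ictal window is kept, near-ictal windows
are excluded, and non-ictal windows are subsampled without replacement to
a 3:1 non-ictal:ictal ratio (all are kept when fewer are available). The
classifier is a 500-tree random forest — bootstrap resampling, trees grown
to full splits, Gini criterion, `mtry = ⌊√p⌋`. No random-forest package is
available in the target environment, so the forest is implemented in C++
inside the package with its own Mersenne-Twister stream; a fixed seed
reproduces the forest bit-identically across platforms. The ictal
likelihood of a window is the fraction of trees voting ictal.

The likelihood trace is smoothed by a leaky weighted integrator
`y_t = α·y_{t−1} + (1 − α)·p_t` with `y_0 = 0` and `α = 0.8`; the source
names but never defines the integrator, and this first-order form makes
the latency correction below exact for a step input. An event opens when
`y > θ` for 5 consecutive segments (10 s); its start time is the start of
the first supra-threshold segment minus the integrator latency
`L = round(α/(1 − α))` segments (8 s at the default α, floored at the
record start) — the stated "accounting for the duration of the
integrator". The event closes after 5 consecutive sub-threshold segments;
the stop time is the end of the last supra-threshold segment, so reported
events hug the detected activity rather than the decay tail. An event
still open at the record end closes there (the source is silent). Ties
(`y = θ`) count as sub-threshold. Post-processing first concatenates
events separated by less than 2 min, then discards any event longer than
15 min; merge strictly precedes discard.

### Threshold calibration

The fixed threshold is calibrated per fold on the training subjects
(only training data are visible to a fold; whether the source calibrated
once globally is not stated). `calibrate_threshold()` sweeps θ over
0.05–0.95 in steps of 0.01 and returns the **largest** θ whose pooled
any-overlap event sensitivity on the training subjects is ≥ 90 %.

Two refinements proved necessary in practice:

1. **Out-of-bag calibration traces.** Scoring training subjects with the
   forest they trained is near-perfect in-sample (votes ≈ 1 inside
   seizures), which pushes the calibrated θ to the top of the grid. The
   calibration traces therefore substitute out-of-bag votes — each
   training row scored only by trees whose bootstrap excluded it — at the
   windows that entered the training set; the remaining windows are
   out-of-sample already.
2. **A safety factor on the operating point.** Even out-of-bag votes are
   optimistic for *unseen subjects*, because other windows of the same
   seizure train the remaining trees. The largest-qualifying θ is
   therefore treated as a critical value, and the operating threshold is
   `θ_op = 0.8 × θ_crit` (`theta_safety`). This implements the stated
   intent that the threshold is "set low" so sensitivity is high at the
   expense of a possibly higher false-detection rate, and it leaves the
   ≥ 90 % training-sensitivity property intact (event sensitivity is
   non-increasing in θ). Without the safety factor, a 5-subject probe
   cohort lost 25 % of held-out seizures to a threshold sitting exactly
   at the sensitivity edge.

## Synthetic cohorts: what they emulate, and what a green test means

No clinical recordings are distributable, so the generator builds a
stated, fixed world:

* **Background EEG**: Gaussian noise shaped to a 1/f power spectrum with a
  Gaussian alpha bump at 10 Hz, band-limited to 0.8–92 Hz by frequency-
  domain masking, scaled to 12 µV RMS, quantized to the 10-bit ±175 µV
  grid and clipped. The four sensors are independent.
* **Seizures**: an evolving oscillation — frequency glide 8→3 Hz with a
  0.35-amplitude second harmonic, slow (~0.3 Hz) amplitude modulation and
  a cosine ramp-up/plateau/ramp-down envelope — applied at full gain on a
  per-subject onset sensor (focal epilepsy has a stable focus) and
  attenuated on the other three as a volume-conduction surrogate
  (forehead pair 0.5, same-side forehead/ear 0.4, ear pair 0.3, diagonals
  0.25). Onset-sensor RMS equals `ictal_snr` × 12 µV; the default
  `ictal_snr = 3` makes seizures clearly visible, as clinical focal-onset
  events in this montage are described to be. The ictal morphology is
  invented: the source shows but does not parameterize waveforms.
* **Cohort structure**: seizure counts 1–6 per positive subject with
  weights chosen to reproduce the clinical cohort statistics (min 1, mean
  2.4, median 2, max 6); durations uniform on 30–180 s, a realistic focal
  range inside the 10 s–15 min envelope of complete seizures; onsets
  > 30 min apart (stricter than the observed ≥ 15 min spacing, so
  near-ictal margins of adjacent seizures never overlap) and ≥ 16 min
  from the record edges. Placement uses the spacing transform (sorted
  uniforms plus mandatory gaps), which is uniform under the separation
  constraint and never fails when placement is feasible; when the
  spec-drawn count cannot fit the drawn stay it is truncated to the
  feasible maximum, while an explicitly requested infeasible count is an
  error. Default stays are scaled to 2–6 h so desk-scale runs finish in
  minutes; the clinical 0.5–5 day stays are one configuration away
  (`stay_hours = c(12, 120)`).

The generator does **not** model artifacts (EMG, electrode pops, poor
contact), inter-sensor background correlation, circadian state changes, or
non-chirp ictal morphologies. A green detection test therefore establishes
that the pipeline recovers separable evolving oscillations from 1/f
background under the stated geometry and timing rules — not clinical
performance. The published clinical numbers were computed on 20 EMU
patients' recordings that are not available, and are deliberately not
asserted anywhere in this package's tests.

Reviewer marks for the agreement machinery are simulated directly at the
annotation level (per-event hit probability, boundary jitter, Poisson
false marks placed clear of true events); they do not model reviewer bias
or correlation between reviewers.

## Evaluation conventions

Any-overlap scoring: a truth event is a true positive iff at least one
detection overlaps it by any positive amount; a detection is a false
positive iff it overlaps no truth event; one detection may validate
several truth events (and vice versa) and is never simultaneously a false
positive. Percent overlap is the fraction of the truth event covered by
the union of its matched detections. Per-subject sensitivity and
precision are percentages; FDR is false positives per hour of the montage
recording (not the nominal stay). Degenerate subjects follow declared
conventions: no truth events → sensitivity undefined and excluded from
cohort means; no detections and no truths → precision 100; truths but no
detections → precision undefined; detections on a truth-free subject →
precision 0. Cohort summaries are unweighted across-subject mean ± SD
[range]. Rule-in metrics are patient-level: a seizure subject counts as
detected if it has ≥ 1 true positive; a seizure-free subject counts as
correctly ruled out if it has no detections at all.

Consensus ("best 2 of 3") is built by rasterizing each reviewer's events
at 1-s resolution, keeping time points marked by ≥ 2 reviewers, and
re-segmenting contiguous runs into events, discarding those shorter than
2 s; the source names the rule without a construction. Cohen's kappa uses
the standard 2×2 agreement form `(p_o − p_e)/(1 − p_e)`; Fleiss' kappa the
standard group form over the two binary categories; degenerate unanimity
returns 1 by convention (needed because rater tables built from real
cohorts can be constant). Both are verified in the tests against
independent brute-force oracles on exhaustively enumerated small tables.

## Seeds and determinism

Every random operation receives a seed derived from one top-level seed
through a purpose-keyed hash (`derive_seed(seed, "purpose")`, values kept
below 2³¹), so adding a pipeline stage never perturbs another stage's
stream. The compiled forest uses its own seeded Mersenne-Twister rather
than R's RNG. A fixed cohort spec regenerates its cohort bit-identically,
and the full simulate → detect → evaluate chain is byte-identical across
repeats — both are asserted in the test suite.

## Known limitations

* The forest is a faithful but minimal CART ensemble (no class weights,
  no variable-importance output); the upstream feature/model selection
  study that fixed these hyperparameters used unavailable data and is not
  reproduced.
* Detection is offline whole-record processing; no streaming mode.
* Only focal-onset, chirp-like synthetic seizures are generated;
  generalized-onset and absence patterns are out of scope.
* EDF support covers the classic container with one EEG signal per file
  (the sensor's native layout), not the full EDF+ annotation machinery.
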