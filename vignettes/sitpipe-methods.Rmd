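---
title: "Methods: behavioral biomarker extraction and evaluation in sitpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral biomarker extraction and evaluation in sitpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the data model

The Simulated Interaction Task (SIT) is a standardized video dialog: an
actress, prerecorded and therefore identical for every participant, talks
about dinner preparation (neutral), food she likes (positive) and food she
dislikes (negative), and after each excerpt the participant answers. The
participant's face and voice are recorded; face and gaze tracking is done
externally (OpenFace) and consumed here as per-frame CSV tables; audio is
consumed as mono PCM WAV.

`sitpipe` models this with three data structures:

* a **frame table** — one row per video frame with timestamp, tracking
  confidence and success flag, 17 action-unit (AU) intensity channels (0-5)
  and presence channels (0/1), and the two gaze angles in radians;
* a **segment schedule** — named half-open intervals `[start, end)` tagged
  with valence and active speaker. The default schedule places six analyzed
  segments on the post-warm-up clock (26 s/24 s/26 s actress excerpts, each
  followed by a 30 s answer window, 166 s in total). The warm-up is not
  analyzed and is not part of this clock. Secondary features use seven
  "parts": the six segments plus the whole-conversation aggregate — this
  reading reproduces the published feature-block dimensions (17 x 6 x 7 =
  714 face statistics), whereas treating the warm-up as a seventh segment
  would not;
* per-recording **voice features** — a fixed 57-field prosody summary.

## Quality control

Frames are dropped when tracking failed or confidence is below 0.75.
Participants are dropped when fewer than 90% of their frames survive or
their mean confidence is below 0.75. The mean confidence is computed over
*all* frames by default (`confidence_scope = "all"`): whether the original
analysis averaged before or after frame filtering is not determinable, so
the choice is explicit and configurable. Real timestamps are always taken
from the file; 30 frames/s is only the synthesis default.

## Facial biomarkers

Per part and AU, *occurrence* is the mean of the binary presence channel
and *intensity* the mean of the intensity channel; empty parts yield `NA`,
never zero. *Social smiling* is the AU12/AU6 occurrence and intensity over
the whole conversation.

*Mimicry* is a windowed, lag-searched correlation between the actress's and
the participant's intensity series for an emotion-relevant AU (joy: AU6,
AU12; disgust: AU4, AU9). For each candidate lag (default 0-3 s in 0.25 s
steps) the participant series is shifted back — mimicry is reactive, the
participant follows the actress, so only non-negative lags are searched —
aligned by nearest timestamp within half a frame period, split into
non-overlapping 10-s windows, correlated per window (windows with fewer
than 10 aligned samples or zero variance are skipped), and aggregated by
the Fisher-z mean, which stabilizes averaging of bounded correlations. The
score is the aggregate at the best lag; lag 0 with a single-element grid
reproduces a plain windowed correlation. Whether the original windows
overlapped, and whether a lag search was performed at all, is not stated in
the source analysis; these defaults are this package's choice.

Part-vs-neutral contrasts (e.g. AU12 in the positive part against the
neutral baseline) are run as *paired statistics* in the statistics stage,
not as subtracted features.

## Gaze kinematics

Per axis: mean angle; mean absolute deviation from the participant's median
angle (median-centering absorbs height and seating differences); mean speed
and acceleration as absolute finite differences scaled by the actual
timestamp deltas. Differences are taken only across consecutive retained
frames whose gap is at most two nominal frame periods — QC-filtered frames
would otherwise create spurious velocity spikes. Derivative units are
rad/s and rad/s²: the magnitudes this produces at 30 frames/s are
consistent with the published descriptive table, whose units are not
stated.

## Voice features

The prosody stack is implemented from standard definitions (the same family
of measures Praat reports); absolute agreement with any particular external
tool is not claimed, and correctness is established by parameter recovery
on synthesized voices.

* **Pitch**: windowed autocorrelation (40 ms frames, 10 ms hop), normalized
  and divided by the window's own autocorrelation, candidate lags within
  [1/500 Hz, 1/75 Hz] (covering adult male and female speech), parabolic
  peak interpolation, voicing threshold 0.45 on the corrected peak. A small
  per-octave score penalty (0.05) prefers the shorter lag among near-equal
  peaks; without it, an isolated subharmonic pick derails the cycle
  extractor's period prediction.
* **Cycles**: within each voiced stretch, successive waveform maxima are
  searched in consecutive windows of one predicted period; peak positions
  are refined by a least-squares parabola over ±3 samples, so period jitter
  is not quantized to the sample grid; local period predictions are clamped
  to ±40% of the stretch median F0 as an octave-error guard. Stretches
  under 3 cycles are dropped; no cycle spans an unvoiced gap.
* **Jitter/shimmer**: the five period-perturbation and six
  amplitude-perturbation measures (local, local absolute/dB, rap, ppq5,
  ddp = 3·rap; apq3/5/11, dda = 3·apq3), pooled across stretches with
  neighbor differences never crossing stretch boundaries.
* **HNR**: per voiced frame `10 log10(r / (1 - r))` with `r` the corrected
  autocorrelation peak, clipped to [-20, 40] dB, summarized by
  mean/median/SD.
* **MFCCs**: Hann magnitude spectrogram (25 ms / 10 ms), 64 triangular mel
  filters from 0 to Nyquist, log with floor 1e-10, orthonormal DCT-II,
  coefficients 0-39 averaged over frames. Only the mean is aggregated; the
  source analysis names means over frames and nothing else.

The 57 voice fields are: F0 mean/SD over voiced frames, 5 jitter, 6
shimmer, 3 HNR aggregates, whole-wave RMS energy, and 40 MFCC means. With
gender appended this gives the published 58-column voice block. The
composition (exactly which measures fill the 58) is a reconstruction — the
source names the families but not the enumeration.

## Secondary features

Each channel in each of the seven parts is summarized by six statistics:
mean, SD, min, max, skewness (g1) and excess kurtosis (g2). The source
lists seven statistics including "time points of maximum", but its printed
dimensions (714 = 17 x 6 x 7 face, 84 = 2 x 6 x 7 gaze) force six per
channel; we drop the time-of-maximum — the only statistic that is not
invariant to reordering frames within a part — and keep the six
order-invariant moments. Gender is counted inside the published 715/85/58
totals (714 + 1, 84 + 1, 57 + 1). Only intensity channels enter the face
block, as forced by the 17-channel arithmetic. Missing values (empty parts)
are imputed by the training-fold median inside the classifier, never at
feature-building time.

## Classifier

Leave-one-subject-out evaluation with nested 3-fold stratified
hyperparameter selection: tree depth and minimum samples per leaf over
{1, 2, 4, 8, 16, 32, 64}², 1000-tree probability forests by default, mean
inner AUC as the selection metric (the source does not name one), ties
broken toward smaller depth then larger leaf (the simpler model). The
held-out probability is the forest's mean per-tree class fraction; the
held-out subject — including its label — never enters training, which the
test suite verifies by label-flipping.

Each tree draws a balanced bootstrap (equal counts per class). The
published decision function is described as involving balanced classes, and
without balancing, leave-one-out folds systematically under-represent the
held-out subject's class by one subject, which measurably depresses
out-of-sample probabilities for that class and biases the null AUC well
below 0.5 at this sample size.

Derived metrics: rank AUC with half tie credit (identical to the normalized
Mann-Whitney statistic), threshold metrics at 0.5, McNemar comparison
against the majority vote (exact binomial p on discordant pairs, plus the
continuity-corrected chi-square), and Spearman correlation of the
out-of-sample probability with severity or age.

## Group statistics

All univariate comparisons are non-parametric: Mann-Whitney U (exact by
enumeration for n1 + n2 ≤ 12 without ties, otherwise tie-corrected normal
approximation with continuity correction) with effect size r = |Z|/√N;
Wilcoxon signed-rank for the paired part-vs-neutral contrasts (exact by
sign enumeration for up to 12 non-zero differences — valid also under tied
magnitudes — otherwise the corrected approximation). Published statistics
of the form "Z = 703" are interpreted as signed-rank sums W; their
magnitudes are incompatible with standard-normal deviates. F0 and HNR are
compared by two-way group-by-gender ANOVA with type-II sums of squares and
generalized eta squared computed as SS_effect / (SS_effect + SS_error),
treating both factors as manipulated (the source's denominator convention
is not stated). Multiplicity is controlled by Holm's step-down within each
feature family (face/gaze/voice); the source corrects for multiple
comparisons without naming a method.

## The synthetic cohort generator

Clinical recordings are not publicly available, so the generator emulates
the study conditions and is itself first-class, tested code. The `"paper"`
preset encodes the published group profiles as generation targets:

* whole-conversation occurrence: AU12 0.40 (NT) vs 0.09 (ASD), AU6 0.12 vs
  0.02; AU12 intensity 0.52 vs 0.16; AU4 intensity 0.03 vs 0.08 in the
  negative part with a common 0.056 baseline elsewhere;
* mimicry coupling 0.19 vs 0.08 (AU6; analogous values for AU12/AU4/AU9)
  with a 0.5 s reactive lag;
* F0 per group and gender (121.68/139.67 Hz male, 209.08/218.91 Hz female)
  and HNR (10.84/8.50 male, 10.32/6.91 female) with the published SDs. The
  descriptive table orders HNR as NT above ASD while the accompanying text
  claims the opposite direction; the preset follows the table, and the
  contradiction is documented rather than resolved;
* equal jitter (0.01) and shimmer (0.05); near-null gaze differences with
  the published means, SDs and speeds.

AU activity is generated as a low-pass-filtered (0.5 Hz) Gaussian latent
process — smooth, with tunable marginal statistics — thresholded per
segment so the expected occurrence hits the target, and rectified and
scaled so the expected intensity does; emotion-relevant AUs mix in the
lag-shifted actress latent with the group's coupling. Subject-level
heterogeneity enters as logit-scale occurrence noise (SD 0.35) and
log-scale intensity noise (SD 0.2) — values chosen once as plausible
between-subject spread. Gaze angles are mean-reverting (AR(1)) series whose
stationary SD and mean absolute frame-to-frame speed match the targets;
acceleration is emergent, not calibrated, and a rough random walk yields
larger acceleration magnitudes than smooth natural eye movement. Voices are
pulse trains (a smooth harmonic-rich von-Mises-shaped glottal pulse) with
per-cycle period and amplitude perturbations calibrated so the expected
local jitter and shimmer equal the targets, plus white noise at the power
implied by the target HNR. Each pulse carries a single amplitude so shimmer
survives at the waveform peaks.

ASD subjects receive a per-subject *effect multiplier* (normal, mean 1, SD
0.3, truncated to [0.2, 1.8]) scaling their deviation from the NT profile;
the synthetic ADOS-like severity score is a linear function of that
multiplier plus noise, so the probability-severity correlation is testable
without clinical data. The `"null"` preset gives both groups the NT profile
and an uninformative severity score. Everything is deterministic under one
root seed, split per participant and stage.

What the generator does *not* emulate: correlated AU co-activation
patterns, speaking/pause structure and verbal content in the audio,
camera-specific tracking artifacts, or age effects on any channel. Passing
tests therefore demonstrate that the pipeline recovers what it measures
under controlled conditions — not that the published clinical effect sizes
would replicate on real recordings.

## Problem sizes used by the tests and the acceptance script

The published protocol (1000 trees, the full 49-point grid, 80 subjects at
30 frames/s with multi-minute audio) is the package default. The test suite
and the acceptance script run the same code on scaled problems chosen once:
cohorts of 40+40 (null calibration, univariate recovery) or 20+20
(classifier effect recovery) at 15 frames/s, 2 s of synthesized voice at
8 kHz per participant, a reduced hyperparameter grid (depth {4, 32}, leaf
8) with 150 trees, mimicry lags {0, 0.5, 1} s, and 10-50 replicates or
seeds per stochastic check. These sizes keep the full synthetic study
reproducible in minutes while exercising every code path; none of the
checked properties (calibration bands, recovery tolerances, orderings) is
adjusted to the scale.

## Known limitations

* Prosody values are not bit-identical to Praat's (different windowing and
  cycle-marking details); recovery tolerances, not tool equivalence, define
  correctness here.
* The leave-one-out AUC remains a noisy estimator at n = 80: even with
  balanced sampling, cohort-level chance correlations between
  high-dimensional features and labels spread the null AUC roughly ±0.1
  around 0.47.
* The expert-rating module evaluates given ratings; it does not model
  raters.
* `apq11` requires a voiced stretch of at least 11 cycles and is `NA`
  otherwise, matching its definition rather than padding.
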