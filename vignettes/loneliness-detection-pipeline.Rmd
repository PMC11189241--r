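---
title: "Objective loneliness detection from multi-device sensing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective loneliness detection from multi-device sensing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Momentary loneliness — "how lonely do you feel right now?", answered on a
0–100 slider several times a day — fluctuates on time scales that
traditional retrospective questionnaires cannot resolve. `lonesense`
implements a fully objective detection pipeline for it: passively sensed
streams from a wrist PPG device (heart rate and heart-rate variability), a
sleep-tracking ring (nightly summaries), and a phone (GPS mobility, calls,
messages, app notifications, screen usage) are aligned to each
self-report, and a per-participant random-forest detector classifies each
moment as lonely or not relative to that person's own median. Because no
public dataset of this kind exists, the package ships a synthetic cohort
generator with known ground truth; every stage of the pipeline is tested
against what the generator planted.

## The synthetic cohort

`simulate_cohort()` emulates the study protocol: 5 EMA prompts/day spaced
3 h apart (jittered up to 1 h, so consecutive prompts stay within a 4-hour
window), 12-minute PPG segments every 2 hours at 25 samples/s, day-long
GPS traces with fixes every 1–5 minutes, AWARE-style phone event logs, and
one ring summary row per participant-night.

The latent loneliness process is a day-level AR(1) (persistence 0.8,
stationary SD 1) plus a smooth within-day sinusoid (amplitude ~0.3 SD,
random daily phase): lonely spells persist across days but also drift
within a day. The observed score is `clip(round(50 + 15*latent + eps), 0,
100)` with response noise SD 5. These constants were chosen once so that
scores use most of the 0–100 range without saturating the clip.

Couplings (`coupling_map()`) are standardized effect sizes per channel:
heart rate rises (~4 bpm/SD), HRV falls (~30%/SD on the IBI jitter scale),
away-from-home mobility falls (fewer visited places, shorter away dwells),
communication rates fall (~33%/SD), and Social-category notifications rise
with the latent state. The default map (all effects 1) is the
"strong-coupling" condition used by the end-to-end tests; `coupling_null()`
gives the zero-signal control. Missing data enter as whole-day device
dropout (watch 7%, phone 5%, ring 10% of days) plus 10% EMA non-response —
rates in the range typical of intensive longitudinal studies; nothing in
the pipeline is told which days were dropped.

What the generator does *not* emulate: real optical pulse morphology and
accelerometer-correlated artifacts, realistic map geography (places live
on an abstract plane), circadian structure in phone usage beyond the
7:00–23:00 activity window, and any feedback from behavior to loneliness.
Passing tests therefore demonstrate that the pipeline recovers the signal
it was designed to recover, not that the same accuracy would be reached on
real participants.

PPG waveforms are realized lazily — each segment row carries a private
seed and `realize_ppg_segment()` reproduces its exact waveform on demand —
because a full cohort holds ~360 million samples. Determinism is
byte-level: the same config and seed give identical files from
`write_cohort()`.

## The PPG chain

Each beat contributes a systolic Gaussian plus a smaller dicrotic bump on
a slow baseline; motion bursts add 0.1–0.5 Hz wander (amplitude ~6x the
pulse) and broadband noise, with burst durations drawn from a mixture
straddling 15 s so both repair paths are exercised.

* **SQA** (`segment_sqa()`): non-overlapping 30-s windows, five features
  (IQR, SD of the PSD, heart-cycle energy range, mean Euclidean distance
  and mean correlation between length-normalized cycles and their mean
  template). A window is noisy iff any feature strictly crosses its
  threshold in the noise direction; thresholds were calibrated once on the
  shipped seeded benchmark (`sqa_benchmark()`), where the class
  distributions are separated by more than an order of magnitude.
* **Reconstruction** (`reconstruct_segment()`): the learned reconstructor
  of the original chain is replaced by a deterministic stand-in. Because
  SQA labels whole 30-s windows but the repair rule concerns sub-15-s
  runs, flagged runs are first localized at sample level by robust
  amplitude deviation. Interior runs shorter than 15 s are replaced by a
  pulse train tiled at the local median IBI whose beat-to-beat deviations
  mirror the neighbouring clean IBIs (so repaired stretches keep local
  variability rather than flattening SDNN), amplitude-matched with a
  0.25-s crossfade. Longer runs and edge runs stay noisy and are excluded.
  The test suite verifies on a one-short-burst benchmark that the
  repaired chain's mean HRV error does not exceed the discard-only error.
* **Peak detection** (`detect_systolic_peaks()`): band-pass 0.5–8 Hz,
  local maxima above 0.6x the block-wise 75th percentile of local-maximum
  amplitudes (so dicrotic maxima fall below threshold at low heart rates),
  300-ms refractory keeping the larger of colliding peaks, and parabolic
  sub-sample refinement — at 25 Hz, without refinement, RMSSD accuracy
  would floor at ~40 ms. IBIs outside [300, 2000] ms or jumping more than
  30% from the previous valid IBI are flagged invalid.
* **HRV** (`compute_hrv_features()`): one value per feature per segment.
  Population (ddof 0) SDs everywhere. Spectral features come from a 4-Hz
  linearly interpolated NN series, linear detrend, Welch PSD (120-s Hann
  segments, 50% overlap), LF [0.04, 0.15) and HF [0.15, 0.4) Hz;
  normalized powers satisfy `lfn + hfn = 1` whenever `lf + hf > 0`.
  SDANN uses complete 1-min/5-min bins; a 12-minute segment has only two
  complete 5-min bins, so SDANN5 is emitted but inherently low-confidence.
  Fewer than 10 valid IBIs marks the whole row missing with a reason.

## Behavioral features

Stay points are maximal fix runs within 150 m for >= 10 min, merged into
places at 150 m; home is the place with the most dwell during 00:00–06:00
local. The ten location features follow the standard mobility set
(variance of latitude, mean/variance of speed, number of places,
home/outdoor durations, mean/SD/longest non-home stay, travel distance),
with the four "needs >= 2 places" features missing-marked otherwise.
Speed uses finite differences with a 10-minute gap rule; travel distance
sums only legs faster than 0.5 m/s, three times the apparent speed of
stationary GPS jitter — without this, jitter during dwells inflates path
sums by tens of percent. "Longest duration type other than home" is read
literally as the duration (minutes) of the longest single non-home stay.
Call/message counts and duration sums, per-category notification counts
(18 Play-store-style categories via the shipped app map, unmapped packages
falling back to Unknown), and screen unlock/duration features complete the
phone set. Missed calls are counted with zero duration. Event-count
features are missing (not zero) in windows where the phone produced no
events or fixes at all.

## Assembly

Features sampled repeatedly per day are aggregated over per-feature
look-back windows from the candidate grid {4, 8, 12, 24, 36, 48} h; the
window ends *at* the EMA timestamp, since a record must not peek past its
label moment. The optimum window per feature maximizes the absolute
Pearson correlation with the continuous 0–100 scores, ties to the shorter
window; features whose correlation is undefined everywhere default to
24 h, flagged. Nightly ring features are exempt: each record takes the
most recent completed night. Columns with (strictly) more than 30%
pooled missingness are dropped. Two imputation methods are compared per
feature — A: the mean of up to two nearest preceding and succeeding valid
samples; B: the participant's mean of all valid values — and the method
winning the majority of per-feature correlation votes (ties to B) is
applied to every feature.

Labels are a per-participant median split of the score series (scores at
the median go to the not-lonely class, deterministically and conservative
toward the negative class); a leakage-safe train-only-median mode exists
behind `median_mode = "train"`. The per-participant median over the full
series is the default reading because each personal model balances its own
labels. All selection steps (windows, imputation) and the z-normalization
statistics use only each participant's earliest-half rows — exactly the
rows that are in the training set of *every* personal model — so no test
row of any model can influence them. Z-normalization is per (participant,
feature) with population SD; degenerate columns (SD < 1e-8) scale by 1 and
are flagged.

## Modeling and evaluation

One personal model per participant: training = that participant's
earliest ceil(n/2) records plus all records of everyone else; test = the
most recent half. The detector is a randomized classification-tree
ensemble (ranger): 100 trees, each grown on a random half of the training
rows without replacement, sqrt(p) candidate features per split, minimum
node size 5, fixed seed. A classical 300-tree bootstrap forest changes
none of the synthetic-cohort conclusions but costs three times as much per
model; with 4 device subsets x 30 personal models per run, the
half-sampled 100-tree ensemble keeps a full evaluation within minutes on
one core while leaving the vote-fraction probability granular at 1%.
Predicted probability is the tree-vote fraction; the class threshold is
0.5 with ties to the negative class. Confusion counts are pooled over all
test rows before computing accuracy, precision, recall, F1, MSE and AUC.
MSE is the mean squared error of the binary predictions, i.e. (FP+FN)/n,
which makes `accuracy + mse = 1` an exact identity. AUC is the rank
statistic with mid-ranked ties. The device ablation re-runs the whole
post-selection assembly and evaluation on each single-device column
subset and on all devices together.

## Explainability

Attributions are path-dependent TreeSHAP values of the vote-fraction
output (implemented natively in C++; covers are recomputed by routing each
tree's in-bag half-sample through it). Probability space was chosen over
margin space because "pushes the prediction toward the lonely class" is
the interpretation the signed summaries need. The implementation is held
to three properties in the tests: local accuracy (base value plus
attributions equals the model output, tol 1e-6, on every test record),
exact agreement with an exhaustive 2^M-subset Shapley oracle on small
ensembles, and symmetry for duplicated features. Aggregation reports mean
|SHAP| per participant x feature, features ordered by cross-participant
mean, plus signed per-participant summaries (mean signed attribution and
the feature-value/attribution correlation).

## Numerical choices and degenerate inputs

Population SD everywhere (generator oracles, HRV, z-normalization) for a
single consistent convention. Constant signals yield degenerate SQA
features and are classified noisy. Flat or single-class inputs error
early with informative messages (single-class training sets, participants
with constant scores, missing night fixes for home detection). All
randomness flows from explicit integer seeds; derived child seeds stay
below 2^31.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
study-scale strong-coupling cohort (30 participants x 56 days, ~8,400 EMA
records, ~20,000 PPG segments), a 10 x 28 zero-coupling control, a
100-segment clean PPG recovery set, the 400-window SQA benchmark, 30
home-detection participants, 100 window-selection replicates, and a
6 x 14 cohort for the SHAP local-accuracy audit. These sizes keep a full
end-to-end run in the tens of minutes on a single core while leaving every
statistical check comfortably powered.

## Known limitations

The SQA thresholds are calibrated to the generator's amplitude scale
(pulse ~1); real deployments would re-calibrate on device data. The
reconstruction and peak-detection stand-ins are deterministic signal
processing, not the trained neural models of the original chain, so
absolute HRV accuracy on real wrist data would differ. Supplementary
phone features beyond the main feature list (keyboard, battery) are out
of scope, as are regression on the raw 0–100 score and any intervention
layer.
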