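---
title: "Detecting fidgets and their cortical correlates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fidgets and their cortical correlates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fidgetr studies *fidgets* — brief, stereotyped startle-like movements of
head-fixed mice (an abdominal flexion with trunk contraction that lifts the
body off the running disk) — and how visual cortical neurons respond when
they happen. The package implements the full analysis chain as a tested,
simulation-backed pipeline: behavioral video classification, optical-flow
magnitude, event-aligned calcium-trace statistics, response-type
clustering, population decodability tests, and behavioral-state modulation
of visual responses. Because the original recordings are not required,
every stage is validated against a synthetic-session generator whose
ground truth is stored separately from its observables.

```{r setup, eval = FALSE}
library(fidgetr)
```

## The synthetic-session generator

`simulate_session()` produces, on a common 30 Hz frame clock: a behavioral
video, per-frame labels (`fidget` / `movement` / `resting`), a dF/F matrix
with per-neuron ground-truth response types, a drifting-grating stimulus
table, and a running-speed trace.

**Video.** The animal is modeled as a textured, deformable elliptical blob
on a static textured background — not a rendered mouse. The classifier
consumes gradient-orientation statistics, so what matters is that the body
has gradient structure and that fidgets deform it the way the real
behavior does: a vertical lift with a half-sine time course (peak a few
pixels), horizontal contraction and slight vertical stretch (the arched
posture). Running bouts instead produce a small periodic sway-and-bob
signature. Defaults: 80x80 px frames, body ~48x27 px, fidget lift mean
7.5% of frame height (6 px), durations uniform over 0.5-1.5 s (15-45
frames), amplitude CV 0.1 (fidgets are strongly stereotyped), light sensor
noise (SD 0.004). Consecutive events are scheduled at least
`min_event_gap_s` apart — by default one full 100-pre/200-post analysis
window (10.2 s), so event-triggered averages contain no echoes of
neighboring events; without this spacing the shared within-session
schedule stamps a session signature into every neuron's mean trace, which
a per-neuron decoder can exploit as spurious area information on a null
cohort. Dense, video-only sessions may lower the gap to 1 s. What the video does *not* emulate: whisking, grooming,
postural idiosyncrasies across mice, illumination drift — so detector
scores on synthetic video are upper bounds relative to real video, and the
published real-data scores serve as lower bounds for the recovery checks.

**Traces.** Each neuron draws a response type from `type_probs` (defaults
are the published prevalences 52.8 / 13.9 / 12.0 / 21.3% for neutral /
phasic / active / depressed) and adds, at every fidget onset, its type's
template scaled to a per-neuron dF/F amplitude, lognormal with median 0.15
and sdlog 0.1. The tight amplitude spread encodes the premise that each
archetype is a stereotyped waveform; larger spreads radially elongate the
clusters and blur the boundary between model selection and noise
modeling. Templates (`response_templates()`) are causal (pre-onset samples
identically zero) and built from GCaMP6f-like kinetics with decay tau
0.7 s: phasic = impulse convolved with the indicator, active = step
(sustained drive), depressed = negative step. Every neuron also carries a
visual response tuned in direction (von Mises, kappa = 2) and temporal
frequency (log-Gaussian, 1 octave SD); a `running_fraction` subset gets a
multiplicative 1.5x gain during running, which gives the modulation module
a recoverable effect of known sign. White Gaussian noise (SD 0.05 dF/F)
completes the trace; temporally correlated noise and neuropil
contamination are deliberately out of scope.

**Cohorts.** `simulate_cohort()` cycles metadata (areas VISp/VISpm/VISal/
VISl; depths 175/275/375 um mapping to layers L2/3, L4, L5 — depth 350 is
treated as L4; Cre lines). With `area_effect = 0` all sessions share one
prevalence vector (a *null* cohort: any decodable area structure
downstream is a false positive). With `area_effect > 0` each area
over-represents one type by that amount (VISp: phasic, VISpm: active,
VISal: depressed, VISl: neutral), a positive control that the decoder must
detect for the null result to mean anything.

## Fidget detection from video

The detector follows the published feature pipeline: grayscale frames are
min-max normalized, power-law compressed (`gamma = 0.5`; the exponent is a
free choice, only "power-law compression" being prescribed), and cropped;
per-frame HOG descriptors use 8 unsigned-orientation bins over 32 px
square cells, one cell per block, no cross-cell normalization; PCA reduces
frames to 50 components (capped at the feature count — a 64x64 crop yields
only 32 HOG features); consecutive one-second groups of reduced frames are
concatenated into non-overlapping block vectors; an RBF SVM classifies
blocks into fidget / movement / resting, with C and gamma grid-searched by
cross-validation. Design choices the source left open, fixed here: a
training block is labeled `fidget` when more than half its frames are
(majority vote); blocks tile the video without overlap; classes are
weighted inversely to frequency so the rare fidget class is not swamped;
the PCA basis is fit on training frames only and never refit at inference
(a guard test asserts refitting changes results). Predicted block labels
broadcast to their 30 frames; a trailing partial block is `resting`.
Training blocks always tile without overlap, but at inference the
one-second window may slide with a sub-block stride (the package's
detection benchmarks use half a block): a 15--20-frame fidget that
straddles a tile boundary has no majority block in one phase of the grid
but does in another, so phase-robust inference takes, per frame, the most
event-like prediction among covering blocks. This raises recall on short
events without costing precision on clean video.

`extract_events()` turns label tracks into events: maximal fidget runs,
runs separated by <= 5 frames merged, merged runs shorter than 10 frames
(~330 ms) dropped as label jitter. Event scoring is any-overlap at the
event level (precision = overlapping predictions / predictions, recall =
recalled truths / truths); frame-level confusion counts are also
available since the level used for the published numbers is unstated.

## Fidget magnitude from optical flow

Dense two-frame optical flow is computed with the Farneback
polynomial-expansion method (quadratic local model under a Gaussian
applicability, poly_n = 7, sigma = 1.5), a 30-pixel averaging window
(rounded up to 31 taps for symmetry), three pyramid levels at scale 0.5
and three warping iterations — all in R via cached banded-matrix
convolutions. An event's magnitude integrates the per-pixel L2 flow norm
over all consecutive frame pairs in the event. For a lift-and-return
movement this integral tracks the total path length of the body, i.e. the
event's amplitude, largely independent of duration — which is what makes
the within-30%-of-maximum stereotypy statistic meaningful.
`magnitude_stereotypy()` reads "within 30% of the maximum" as
`m >= 0.7 * max(m)`.

## Event-aligned responses and the four types

`align_and_zscore()` crops 100 pre / 200 post frames around each onset
(events without a full window are dropped and counted) and z-scores each
trial by its own 100-frame baseline; zero-SD baselines exclude the trial
(or are epsilon-stabilized on request). Neurons need >= 3 usable trials to
be clustered — a one-trial "mean" is noise. Mean post-onset z-traces are
clustered with k-means++ (hand-seeded, Hartigan-Wong refinement, best of
`nstart` restarts).

The number of clusters is chosen by the gap statistic
(`cluster::clusGap`, squared-distance dispersion, uniform references in
the scaled-PCA frame, 20 references). The selection rule is
`globalSEmax`: the smallest k whose gap reaches the global maximum minus
its standard error. The classic one-standard-error rule ("smallest k with
gap(k) >= gap(k+1) - s(k+1)") is available via `se_method`, but it
misreads this data family: with one dominant type (~53% neutral) the gap
curve dips at k = 2 below its k = 1 value before rising sharply to its
true maximum at k = 4, and the classic rule stops at the first
inequality — at k = 1 — even when k-means at k = 4 recovers the generating
partition exactly. The global-maximum variant uses the same standard-error
machinery but reads the whole curve.

Clusters are named by centroid statistics: with M the mean post-onset z,
P the signed peak, and L the fraction of the post window above half peak,
a centroid is neutral (|M| <= 0.25, |P| <= 0.5), depressed (M < -0.25),
phasic (M > 0.25, L <= 0.5) or active (M > 0.25, L > 0.5); anything else
falls back to the nearest archetype with a warning. The thresholds are
package conventions — the source never states how clusters were named.

`apply_threshold_criteria()` implements the dF/F modulation criteria
(mean post > 6%, or max post > 5%, compared in magnitude so depressed
cells are judged by their deflection depth): non-neutral neurons failing
the criterion become `criteria neutral`; neutral neurons are never
promoted, so stricter thresholds always select subsets.

## Decodability of area, layer and Cre line

`embed_responses()` projects 200-sample mean post-onset traces with UMAP
(min_dist = 0, n_neighbors = 20, 2-D) or the robustness variants
(n_neighbors 5 or 200, 3-D UMAP, PCA-10). `train_and_score_decoder()`
uses a stratified 85-15 split, balances classes *after* the split by
subsampling each to the smallest class count (independently in train and
test — the wording "in the training and test sets" reads most naturally as
after-split), grid-searches a gradient-boosted-tree classifier (depth
{2, 4, 6} x learning rate {0.1, 0.3}, 100 rounds) with five-fold CV, and
reports per-class F1 = TP / (TP + 0.5 (FP + FN)) on the held-out split.
`shuffle_baseline()` repeats the identical protocol on permuted labels
(20 repetitions by default) to estimate chance. The package-level claim
is two-sided: a null cohort must decode within 0.05 of its shuffled
baseline, and a positive-control cohort (area_effect 0.3) must beat its
baseline by more than 0.15 — otherwise a "null" result would be vacuous.

## State modulation of visual responses

`preferred_condition()` picks each neuron's (direction, TF) with the
largest mean stimulus-window dF/F (ties break toward lower direction,
then lower TF). `state_modulation()` computes Cohen's d between state and
non-state frames of preferred-condition trials, with the SD "norm" read
as the Euclidean norm sqrt(s1^2 + s2^2) (a pooled variant is available).
Running frames require speed > 1 cm/s sustained >= 1 s; fidget and
running masks are mutually exclusive (fidget wins). Per-cell significance
uses two-sided two-sample KS tests, BH-corrected at q < 0.05 — the same
test family the source declares globally, though it also cites t tests in
places; the KS choice is recorded rather than resolved.
`modulation_interaction()` reports the covariance and correlation of the
two d vectors and the fraction of running-modulated cells that are also
fidget-modulated. `tuning_metrics()` adds DSI = (R_pref - R_null) /
(R_pref + R_null), preferred orientation (direction mod 180) and
preferred TF; the formulas are standard-practice choices.

## Problem sizes, determinism and limitations

The shipped test-suite and acceptance runs use deliberately scaled
problems: gap-statistic recovery on 2,000 neurons (k up to 6, 20
references), prevalence recovery on 5,000 neurons in a 5-minute session,
detector training on five 4- or 10-minute sessions with ~8-20 fidgets
each against one held-out session, 200 flow-scored events, and
12-session cohorts of 150 neurons for the null/positive decoding checks.
Every stochastic step derives its stream from one integer seed via fixed
offsets, so identical configurations reproduce byte-identical tables.

Known limitations: the generator's video realism is minimal by design
(the detector's synthetic scores bound real-data behavior only from
above); trace noise is white; running modulation is purely multiplicative
on visual responses; trials overlapping neighboring events are kept
(flaggable); and the Farneback implementation is single-threaded R tuned
for small cropped frames, not a general video-rate flow engine.
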