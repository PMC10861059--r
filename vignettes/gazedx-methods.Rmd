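---
title: "Methods: from gaze samples to diagnosis with difference-of-fixation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gaze samples to diagnosis with difference-of-fixation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedx)
```

## The problem

In the preferential-looking paradigm a child watches a split-screen video
with dynamic geometric imagery on one side and dynamic social imagery on
the other. A subset of autistic children attend far more to the geometric
side, which makes the paradigm attractive for objective screening. The
classical analysis reduces each child to a single number — %Geo, the share
of fixation time on the geometric half — and thresholds it. `gazedx`
implements that analysis, and goes beyond it: it learns *where the groups'
attention differs on every video frame* and uses features indexed at each
child's fixations for classification, which preserves spatiotemporal
information the scalar statistic discards.

## Fixation processing

Raw 60 Hz gaze samples are converted to fixations with a velocity-threshold
(I-VT) filter. The point-to-point angular velocity between consecutive
valid samples is compared with a threshold (default 30°/s — the common
I-VT default; the value is configurable because the reference protocol
does not state it). Maximal runs in which every between-sample velocity
stays below the threshold become fixations; runs are also broken by
recording gaps of more than two sample periods and by intervening invalid
samples, so no gaze is fabricated across tracker dropouts. Segmenting on
sample *pairs* rather than classifying individual samples keeps the filter
exactly symmetric under time reversal, which the test-suite exploits as an
invariant.

Post-processing follows the published chain: adjacent fixations separated
by at most 75 ms and 0.5° are merged (centroid distance, duration-weighted
merge), *then* fixations shorter than 100 ms are discarded. Merging first
lets two short neighbouring samples of the same underlying fixation
survive as one — the order is a config flag. A recording enters analysis
only when total fixation time reaches 15 s (about a quarter of a one-minute
stimulus); the synthetic pipeline scales this floor down with clip length.

All angular constants pass through an explicit geometry object (screen
size, viewing distance, stimulus-to-screen mapping). The default maps a
1281×720 stimulus onto a 1680×1050 display at 60 cm, letterboxed; the
chord formula `2 d tan(θ/2)` is exact and round-trips to machine
precision.

## Difference-of-fixation maps

For each frame and group, fixation centroids are overlaid in a binary map
(set semantics: a pixel is 1 no matter how many fixations land on it),
smoothed with an isotropic Gaussian of 1° bandwidth truncated at 3σ, and
normalised to unit sum. With reference-group heatmap $I^-$ and
contrast-group heatmap $I^+$, the difference image is $I = I^- - I^+$ and
the DoF map is

$$D = \frac{1}{1 + e^{-I/\sigma_I}},$$

where $\sigma_I$ is the **population** standard deviation of $I$ over the
frame — it normalises a fixed image rather than estimating a sample
parameter, and it makes $D$ invariant to any positive rescaling of $I$.
Ties sit exactly at 0.5; swapping the groups maps $D \mapsto 1-D$. When
$\sigma_I = 0$ (identical maps, e.g. a frame nobody fixated) the map is
defined as the constant 0.5, the symmetric limit of the transform. The
orientation (which group is "white") follows the convention that the
reference/control group is bright; it is an argument, not a constant.

Fixation maps are built at stimulus resolution and downsampled to the
training-target resolution (28×28 at paper scale, 7×7 for the tiny preset)
by exact area averaging *before* the sigmoid; downsampling the smooth
heatmaps rather than the post-sigmoid maps keeps the difference image a
difference of probability masses.

## The saliency network

The per-frame DoF maps are the training targets of a video saliency
network: a two-stage convolutional encoder (3×3 convolutions, ReLU, 2×2
average pooling), a static attention gate (1×1 convolution + sigmoid, the
features are multiplied by $1 + A$ so attention amplifies rather than
masks), a convolutional tanh recurrence over frames whose hidden state is
the per-frame feature volume, and a 1×1 sigmoid decoder. Two presets fix
the operating points: `paper` (256 channels, 28×28 output, 112×112 input)
and `tiny` (16 channels, 7×7 output, 28×28 input) for desk-scale tests.
The recurrent unit is an Elman-style convolutional tanh cell; it fulfils
the architecture contract (encoder + attention + convolutional recurrence
+ decoder) with far fewer parameters than a convLSTM, which matters for a
pure-R implementation, and the end-to-end tests show it memorises and
generalises at the scales exercised here. Pretrained weights are not
distributed; models are initialised He-Gaussian from a seed, and a
weight-import hook is unnecessary because every experiment in this package
fine-tunes from scratch.

Training minimises the sequence loss $L_d = \sum_t L(Y_t, Q_t)$ with

$$L = L_{KL} + 0.1\,L_{LCC} + 0.1\,L_{NSS}.$$

For $L_{KL}$ both maps are regularised by $\varepsilon = 10^{-7}$ and
renormalised to distributions; $L_{LCC}$ and $L_{NSS}$ operate on raw
values, mirroring common saliency-metric practice. $L_{NSS}$ uses the
continuous DoF map as its target weighting. Degenerate inputs are defined,
not fatal: a constant prediction or target makes the correlation and NSS
terms 0 with a warning (an all-zero target is an error, since KL is then
meaningless). Optimisation is Adam at learning rate $10^{-4}$ for 20
epochs. "Batch size one" is realised as one optimiser update per truncated
backpropagation-through-time chunk (default 8 frames, carried hidden state
detached between chunks), because frame-wise batching is incompatible with
recurrence. All gradients — loss with respect to prediction, and every
parameter through decoder, recurrence, attention and encoder — are
analytic and validated against central finite differences at $10^{-4}$
(loss) and $10^{-11}$ (parameters, relative) in the tests.

## Features and classification

The recurrent feature volume of each frame is bilinearly upsampled 4×
(edge-replicating, constant-preserving). For every fixation, the volume of
the fixation's **onset** frame is indexed at the grid cell proportionally
nearest the centroid, giving one C-vector per fixation stage
(saccade–fixation pair); a duration-averaged variant is a config option.
The first K stage vectors are concatenated in temporal order and
zero-padded to exactly K·C entries. A linear SVM (L2 penalty, C = 1,
features unstandardised by default; an optional scaler is fitted within
each training fold) is evaluated by leave-one-out cross-validation — one
fold per child, the protocol of choice for small imbalanced cohorts.
Probabilities come from a Platt sigmoid fitted on each training fold's
decision values; the SVM library's built-in calibration is avoided because
its internal cross-validation draws from a random stream outside R's seed
control. Pooling the per-fold probabilities yields the ROC AUC via the
rank (Mann–Whitney) estimator with tied ranks averaged.

By default the DoF targets and the fine-tuned network are built once from
the full cohort before cross-validation — the apparent protocol of the
published pipeline. This leaks group-level information into the features;
a `fold_safe` mode rebuilds targets and model per fold without the
held-out child. The null-cohort acceptance check (below) shows the default
protocol's optimism stays modest at these scales, but real applications
should prefer `fold_safe`.

The severity task is the same machinery on an ASD-only cohort split into
moderate (reference) and high (contrast) strata by calibrated severity
scores (5–7 vs 8–10), with a **separately** fine-tuned network — sharing
the diagnosis model is possible via config but not the default, since the
two contrasts answer different questions.

## Baselines

* **Threshold rule**: positive iff %Geo > 69 (strict), the published
  preferential-looking cut-off.
* **Handcrafted features**: a 128-point subsample of the raw gaze
  trajectory, mean fixation duration, mean gaze velocity, age and gender,
  fed to a random-forest regressor (output thresholded at 0.5) and a
  decision-tree classifier under the same LOOCV. The tree's minimum-split
  size scales with the training-fold size so the baseline remains
  non-degenerate on desk-scale cohorts.
* **Summary-statistic t tests**: pooled-variance two-sample t tests (df =
  n₁+n₂−2) computed directly from group mean/SD/n, reproducing all four
  published %Geo comparisons to ±0.01; Welch is available but the pooled
  form is the default because it matches the published degrees of freedom.

## The synthetic generator

The generator defines the study conditions for every test. Stimuli are
grayscale split-screen frames — a drifting grating (geometric) versus
moving Gaussian blobs (social) — with the geometric side alternating
across scenes and the schedule emitted as the AOI table. The default frame
is 128×72, the reference 16:9 aspect at one-tenth scale; analyses are
resolution-independent because all angular quantities go through the
geometry object, and full-scale frames are a single argument away.

Gaze is simulated at the fixation level: per-participant %Geo is drawn
from a normal distribution truncated to [0, 100] with the published group
structure as defaults (ASD 49.37 (24.14), TD 35.97 (18.58); moderate 48.21
(23.82), high 50.98 (25.00)); fixations alternate with saccade gaps
(log-normal durations, median ≈ 250 ms; exponential gaps ≈ 57 ms), land on
the geometric side with probability %Geo/100, and emit 60 Hz samples with
isotropic angular jitter (default SD 0.15°, matching a tracker accuracy of
about half a degree at the reduced scale). Saccade-gap samples are emitted
as invalid, as screen trackers commonly report during rapid movement. The
generator does **not** model smooth pursuit, calibration drift, or
photorealistic social content — so passing tests demonstrate the
pipeline's mechanics and statistical behaviour, not clinical performance
on real populations.

## Problem sizes and numerical choices

The test-suite and the acceptance script run the `tiny` preset throughout:
61-frame (~2.5 s) clips for pipeline tests, 24-frame clips for training
sanity, ~30 s recordings for the %Geo round trip, cohorts of 10–16 per
group. These sizes keep the whole suite under two minutes while leaving
every mechanism — detection, merging, DoF construction, training,
cascading, cross-validation — fully exercised. Other fixed choices:
$\varepsilon = 10^{-7}$ inside KL; Gaussian kernels truncated at 3σ with
zero padding and renormalisation; area-average resampling for downscaling
and bilinear for upscaling; ties in the fixation-length sweep resolve to
the smallest K; coordinates are 0-based with origin top-left and time
intervals are half-open in milliseconds.

## Known limitations

* The published clinical results (94.59 % / 100 % / 76.47 % diagnosis
  accuracy/sensitivity/specificity, AUC 0.96; 94.74 % / 87.50 % / 100 %,
  AUC 0.99 for severity) were obtained on an undeposited cohort; this
  package reproduces them only as metric arithmetic from the published
  confusion counts, and reproduces the *behavioural properties* of the
  pipeline on synthetic cohorts.
* The default (non-fold-safe) protocol leaks cohort-level DoF information
  across folds, as discussed above.
* The recurrent cell is a convolutional tanh recurrence, not an LSTM; at
  paper scale (256 channels) training in pure R is possible but slow.
* The I-VT velocity threshold and the merge-distance interpretation
  (centroid vs gap distance) are unspecified in the reference protocol;
  both are explicit configuration here (30°/s, centroid distance).
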