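---
title: "Decoding movement intention from high-density sleeve EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding movement intention from high-density sleeve EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdemg)
```

## The problem

After stroke, many people retain measurable forearm muscle activity even
when the hand itself barely moves. A high-density surface-EMG sleeve —
64 to 75 bipolar channels wrapped from elbow to wrist, sampled at 3 kHz —
captures a spatial map of that activity. `hdemg` implements the full chain
needed to turn such recordings into a movement-intention decoder for
rehabilitation use: preprocessing, feature extraction, alignment of cue
labels to actual muscle activity, classifier training, evaluation, and a
debounced online decoder. Because clinical recordings cannot ship with a
package, a synthetic sleeve simulator with known ground truth makes every
stage testable.

## Signal model of the simulator

`simulate_emg()` generates a channels × time µV signal over a cue schedule
(8 s lead-in rest, then movement cues alternating with rests; cue and rest
durations are uniform on 4–6 s for the stroke profile and 2–3 s for the
able-bodied profile):

* every channel carries band-limited (20–400 Hz) Gaussian baseline noise
  (default RMS 10 µV) plus a 60 Hz mains sinusoid (default 2 µV,
  channel-specific phase);
* each movement owns a Gaussian spatial blob of channel weights on the
  electrode grid. Blob centers are a deterministic hash of the movement
  label, constrained to the flexor or extensor sectors according to the
  movement's musculature, so patterns are anatomically plausible and
  reproducible. The blob SD grows with an impairment parameter
  (`1.2 + 2.4 × impairment` grid units), de-localizing activity the way
  impaired EMG is;
* during a movement's *true* activity interval each channel receives extra
  band-limited noise whose RMS is the blob weight times a target SNR
  (default 15 dB over baseline), times a per-movement observed-movement-score
  factor (0, 0.33, 0.66, 1 for scores 0–3), times a per-cue log-normal
  effort factor (sdlog 0.15);
* the true interval lags the cue by independently drawn onset and offset
  reaction latencies, uniform on 0.2–1.2 s by default — inside the 2 s
  alignment bound, and chosen so that the mean injected shift (~0.7 s) is
  of the order of reaction delays seen in impaired subjects.

SNR, baseline level and effort variability are free parameters of the
simulator, not estimates from any subject population; they were fixed once
at values a surface-EMG practitioner would call realistic. What the
simulator deliberately does **not** model: motor-unit physiology, volume
conduction, electrode-skin impedance, motion artifacts, or inter-session
electrode shift. Tests passing on simulated data therefore demonstrate the
*correctness of the pipeline machinery and the statistical behavior of the
algorithms under known ground truth* — not clinical-grade performance on
real stroke EMG.

## Preprocessing

Filtering is a 10th-order Butterworth band-pass (20–400 Hz) plus a 60 Hz
notch (Q = 30, narrow enough to spare the band). Two numerical choices
matter:

* **Causal, forward-only filtering everywhere.** An online decoder cannot
  look ahead; using the same causal filters offline keeps train, test and
  online features on an identical scale. The filter state is carried across
  streaming frames, so stream and batch filtering agree bit for bit.
* **Second-order sections.** At order 10 the expanded transfer-function
  coefficients are numerically unstable (poles leave the unit circle under
  coefficient rounding), so the design is done in zero-pole-gain form —
  analog prototype, band transform, bilinear map with edge prewarping —
  and realized as five biquads plus the notch biquad.

Features are per-channel RMS over consecutive non-overlapping 100 ms
windows (300 samples at 3 kHz; a trailing partial bin is discarded, never
padded). Each prediction sample stacks the current and three preceding
bins — 400 ms of context. Normalization to per-feature mean 0, variance 1
is fitted on training data only and reused for test and online data; it is
applied per channel *before* stacking so all four lags of a channel share
one scale (the alternative, normalizing after stacking, would give each lag
its own statistics; with stationary training blocks the two are nearly
identical, and the pre-stacking choice is what an online decoder can do
naturally). Variances are floored at 1e-12 so constant channels map to 0.

A bin belongs to the segment containing its start time (half-open bins).
For classifier training, the middle 2.5 s (stroke) or 1.5 s (able-bodied)
of every cue and rest segment is extracted and the first 3 bins of each
window are dropped because their stacked context reaches outside the
window: 22 prediction samples per cue at 2.5 s, 12 at 1.5 s. Windows are
selected by bin centers, so the count per segment is exact regardless of
where a segment's boundaries fall inside a bin.

## Dynamic cue alignment

Cue labels assume the subject moves exactly when cued; in reality EMG
onset lags the cue, variably so after stroke. `dynamic_shift()` treats the
across-channel mean of normalized RMS as a per-bin summary signal and fits
a piecewise-constant model with movable breakpoints: the objective is the
sum over segments of squared residuals around the segment mean, and each
boundary between consecutive segments is moved to minimize it. The paper-
level description leaves the optimizer open; here it is exhaustive
per-boundary coordinate descent on the 0.1 s bin grid, sweeping boundaries
in temporal order until a full sweep moves nothing (cap 50 sweeps). Ties
break toward zero shift. Constraints: every shift is bounded by ±2 s of the
boundary's original position, boundaries stay ordered, and every segment
keeps at least one bin. Both directions of shift are allowed by default
(`forward_only = TRUE` restricts to delays). On 3-segment instances the
coordinate descent provably reaches the same optimum as exhaustive joint
search (tested), and SSR is non-increasing by construction.

Static shifting (every interior boundary moved by a constant, 0.8 s as an
offline baseline, 0.3 s online) and `shift_fraction()` (how much of the
label stream an alignment changed) complete the module.

## Classifiers

Three decoders operate on identical stacked-RMS samples:

* **PCA + logistic regression** and **PCA + RBF-SVM.** PCA (training data
  only) keeps the fewest components explaining ≥ 95% of variance.
  Hyperparameters (C for LR; C and gamma for SVM) are tuned on a log grid
  spanning 1e-4 to 1e4 (9 points per axis — the grid density is this
  package's choice; only the range is canonical) by stratified fivefold
  cross-validation, ties toward the smallest C then gamma; the winner is
  refitted on all training data. The LR is glmnet's multinomial ridge with
  lambda = 1/(nC), fitted along a warm-started descending path for
  convergence. SVM class probabilities are a deterministic softmax over
  per-class sums of signed pairwise decision values rather than Platt
  scaling, because libsvm's internal Platt calibration is randomized
  outside R's RNG and would break seed-reproducibility; nothing downstream
  depends on SVM probabilities (the online decoder uses the network).
* **A multilayer perceptron** — input (channels × 4) → 1000 → 500 → classes,
  batch normalization and ReLU after each hidden linear layer, 20% dropout,
  softmax output. Training: label-smoothing cross entropy (true class 0.9,
  remainder uniform), Adam, one-cycle learning rate (cosine warm-up over
  the first 30% of steps from max/25 to the 1e-3 peak, cosine anneal to
  max/1e4), up to 400 epochs with early stopping on a 10% validation split
  (patience 20, best weights restored — the concrete early-stopping rule is
  a package choice). The network, its backpropagation (including through
  batch normalization) and the optimizer are implemented in base matrix
  algebra; gradients are verified against finite differences in the test
  suite, and the forward pass against an independent reimplementation.

Hard labels are the probability arg-max with ties to the lowest class
index, Rest first. Class imbalance is left unweighted; subset analyses
rebalance by sampling instead (below).

## Evaluation

* **Bin accuracy**: fraction of 100 ms bins decoded as the ground-truth
  label.
* **Chance level**: the majority-class (Rest) fraction — the best
  label-independent strategy.
* **Success rate**: a cue succeeds if ≥ 1 s (10 consecutive bins) strictly
  inside the cue is decoded as the cued class; runs crossing a cue edge do
  not count. Rest periods are excluded from the denominator by default;
  `include_rest = TRUE` exposes the other reading, since the canonical
  definition leaves it open.
* **Movement subsets**: binary Rest/Move (all movements collapsed), the
  fixed {Rest, Hand Close, Hand Open} triple, or Rest plus the top-k
  movements by per-class accuracy (computed on training data — never on the
  test set). In all modes Rest is refilled to 50% of the dataset using the
  bins of the rest cue immediately preceding each retained movement, taken
  in temporal order, so the majority-class chance level of a subset is 0.5
  by construction.

The experiment runner holds out the *final* fraction of recording blocks
for testing and asserts the chronology (no training sample postdates a
test sample), mirroring calibration-then-use deployment.

## Online decoding

The online policy avoids state flipping with two rules: a candidate class
(arg-max) only counts when its probability exceeds 0.6, and the decoded
state only changes after 2 consecutive qualifying bins. The threshold is
applied to *every* bin of the pending run — the stricter of the two
possible readings, chosen for maximal flip resistance — and a
sub-threshold bin resets (not pauses) the run. `replay()` feeds a
recording through the exact causal chain (filter continuation → frame RMS →
train-stats normalization → 4-bin history → model → policy step); carrying
filter state across frames makes replay bit-identical to batch processing,
which the tests assert. Cue labels are shifted 300 ms when scoring online
streams, the conventional reaction-time allowance.

## Problem sizes in the checks

The package's statistical checks run on deliberately small instances: cue-
shift recovery uses 4 movements × 2 repetitions per seed over 20 seeds
(test suite) and 10 seeds (acceptance script); the three-decoder comparison
uses the full 12-movement set, one repetition per block, three blocks per
seed, with the network trained for 50 epochs — a scaled-down stand-in for
the full 400-epoch recipe that preserves the architecture and training
policy. These sizes were chosen so the whole suite runs on a laptop-class
single core in minutes while leaving each property comfortably measurable.

## Known limitations

* Simulated EMG is amplitude-modulated band-limited noise; spectral shape
  does not change between rest and movement, so decoders lean entirely on
  spatial-amplitude patterns, as the RMS feature set assumes.
* The LR/SVM surrogate probabilities are uncalibrated (ordering-faithful
  only).
* EDF export quantizes to 16 bits and drops schedule/ground-truth
  metadata; the native RDS format is lossless.
* Recovery guarantees for the alignment optimizer are empirical beyond the
  3-segment case, where it is verified against exhaustive search.
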