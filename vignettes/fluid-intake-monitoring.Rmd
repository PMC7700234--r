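---
title: "Hierarchical fluid-intake monitoring from a wrist-worn IMU: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical fluid-intake monitoring from a wrist-worn IMU: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fluidintake)
```

## The monitoring problem

Dehydration is a common, largely preventable risk in older adults and
chronically ill patients, and self-reported drink diaries are unreliable.
`fluidintake` implements a fully automatic alternative: from a single
wrist-worn inertial sensor (tri-axial accelerometer, range ±16 G, and
tri-axial gyroscope, range ±2000 deg/s, sampled at 128 Hz) it answers three
nested questions:

1. **When did the wearer drink?** — binary classification of sliding
   windows into *Drinking* vs *Other*, among confounding activities that
   share the hand-to-head motif (answering a phone, combing hair, eating
   with the hands or with a spoon).
2. **When, inside a drink, did fluid actually flow?** — five-class gesture
   spotting of *Fetch, Lift, Sip, Drop, Release* within each detected
   drinking event.
3. **How much was ingested?** — regression of the intake amount in grams
   from features of the spotted sip gesture.

The hierarchy matters because the sip sub-gesture, not the whole drinking
activity, carries the amount information: the container-handling phases
around it vary in tempo for reasons unrelated to how much is drunk, so
isolating the sip concentrates the signal.

## Pipeline and models

**Smoothing.** All channels pass a trailing moving average of 16 samples
(125 ms). The filter is causal with a shrinking warm-up window, so event
onsets never leak backwards in time and the same code would work in a
streaming setting. The filter width is the only smoothing parameter.

**Windowing.** Signals are cut into overlapping windows: 160 samples with
50% overlap (hop 80) for detection, 16 samples with 50% overlap (hop 8)
for spotting. A window's ground-truth label is the label covering the
majority of its samples, with ties resolved to the label of the first
sample — the annotation convention the package applies uniformly, since
interval annotations are sample-indexed, 0-based and half-open throughout.
Trailing samples that do not fill a window are dropped.

**Features.** Eleven axes are derived per sample: the six raw channels,
the Euclidean norms \(a_{norm}\) and \(\omega_{norm}\) of the
acceleration and angular-velocity vectors, and the acceleration magnitudes
in the horizontal, coronal and sagittal planes
(\(a_{norm,xy}, a_{norm,yz}, a_{norm,xz}\)). Eight statistics per axis —
mean, standard deviation, variance, maximum, minimum, range, kurtosis,
skewness — give the 88-dimensional window feature vector; amount
estimation appends the sip duration in seconds as feature 89, the only
time-domain feature. Numerical conventions (the references leave them
open, so they are fixed and versioned here): population (n-denominator)
variance, non-excess kurtosis (normal → 3), moment-based skewness, and
kurtosis = skewness = 0 on zero-variance windows so every vector is
finite.

**Detection.** Six interchangeable window classifiers are provided:
AdaBoost over CART weak learners (the default; SAMME weight update, 30
rounds of depth-3 trees), a single CART tree, random forest (100 trees,
minimum leaf size 1), Gaussian naive Bayes, k-nearest neighbours (k = 3),
and a linear SVM. Predictions then pass two rule-based corrections, in
fixed order:

* *fragment revision* — a maximal run of one or two windows whose label
  differs from identical flanking runs is rewritten to the previous run's
  label. The scan is one left-to-right pass over the original run
  structure, so an edit never re-triggers on its own output;
* *duration threshold* — any surviving Drinking run spanning strictly
  less than 2 s (`((n − 1)·step + window_size) / f_s`) is relabelled
  Other, because a complete fluid-intake activity cannot be shorter.

**Spotting.** Inside each detected event the same feature machinery runs
at the 16-sample scale; a random-forest classifier (k = 11 for the k-NN
alternative) labels windows with the five gestures, followed by the same
fragment revision. Maximal Sip runs become sip intervals; multiple sip
runs in one event are all kept and their durations summed, the
conservative generalisation of the one-sip-per-drink assumption.

**Estimation.** Five regression families map the 89 sip features to
grams: ordinary linear regression, Nadaraya–Watson Gaussian-kernel
regression (Silverman rule-of-thumb bandwidth on standardised features —
the name "Gaussian kernel regression" is otherwise undefined in the
source material, and Nadaraya–Watson is its standard reading), and
eps-SVR with linear, cubic-polynomial and RBF kernels at library-default
cost and epsilon. Features are standardised with training-fold mean and
standard deviation before every kernel model; mixed-unit features make
this mandatory. Estimates are clipped below at a small epsilon — negative
grams are meaningless — and flagged when clipped. A *container-dependent*
estimator trains on drinks of one known container type (can, PET bottle,
handleless mug, handled mug); container identity is metadata carried with
each drink, never inferred from the signal.

**Evaluation.** Everything is validated leave-one-subject-out (LOSO):
each subject is held out in turn and all models are retrained without it.
Detection is scored window-level (post-correction) with sensitivity,
precision, specificity, accuracy; spotting with one-vs-rest sensitivity
and precision per gesture plus their unweighted five-class means; amounts
with the mean (signed) percentage error MPE and mean absolute percentage
error MAPE, so `MAPE ≥ |MPE|` always. Zero-denominator metrics are
reported as undefined (`NA`), never as 0. Detected events are matched to
annotated drinks by maximal sample overlap; unmatched detections count as
false alarms, unmatched drinks as misses, and only matched drinks enter
the amount metrics so both estimation configurations share one
denominator.

### Situations (1) and (2)

`run_hierarchical_eval()` compares two configurations per drink:

* **situation (1)** — the whole detected drinking event is used directly:
  its 88 statistics plus its duration substitute for the sip features;
* **situation (2)** — the spotted sip gesture supplies the features, with
  the summed sip duration as feature 89.

Amount estimators are trained on *recognized* drink data: every subject's
drinks are first processed by a detector and spotter that never saw that
subject (its own held-out fold), and each fold's estimators are fitted on
the recognized features of its training subjects. Training on clean
annotated boundaries while predicting pipeline output would mix two very
different feature distributions — near-zero-variance statistics from pure
sip plateaus explode after standardisation when the test sips include a
mislabelled edge window — and the measured error would reflect that
artifact rather than the method. Drinks in which spotting finds no sip
window fall back to situation-(1) behaviour (whole-event features through
the whole-event model) and are flagged; they are excluded from sip-model
training.

## The synthetic cohort generator

The package ships a generator emulating a scripted laboratory protocol so
the full pipeline is exercisable end to end: 20 subjects × 5 trials, each
trial the activity sequence A, FI₁, C, FI₂, H, FI₃, S, FI₄, A (phone,
comb, eat-with-hands, eat-with-spoon interleaved with four drinks from
can, bottle, handleless mug, handled mug), separated by 1–3 s idle gaps —
900 labeled activities in all. Containers start at 240/330/280/300 g of
water, are drained by subtraction across trials and refilled before the
fourth trial.

**Signal model.** Each activity is a set of raised-cosine angular-velocity
bumps on activity-specific axes; wrist pitch and roll are the discrete
integrals of the corresponding gyro channels, and the accelerometer
channels are the gravity vector in the rotated sensor frame — so the
noise-free acceleration norm is exactly 1 G, a property the tests exploit.
Gaussian tremor (per-subject sd 0.012–0.028 G; ×100 on the gyro, in
deg/s) is added throughout. Bumps are discretely normalised so every
self-contained activity returns exactly to zero tilt.

A drinking event is Fetch (yaw swing out), Lift (pitch up to the
per-drink sip tilt), Sip (a near-static tilted plateau), Drop, Release.
Confounders reuse the same vocabulary at different parameters: a phone
call holds a higher tilt for longer; combing adds a 2 Hz roll
oscillation; eating repeats short lift cycles; eating with a spoon
repeats lift–hold–return cycles, deliberately the closest pattern to
drinking and the designed hardest confusion.

**Amounts.** The sip is the amount-bearing variable:
`actual_g = sip_rate[container] × sip_duration × (1 + ε)`,
`ε ~ N(0, 0.10)`, truncated to stay positive and within the remaining
fill. Base rates are 14/20/10/22 g/s for can/bottle/handleless/handled
mug — deliberately distinct, so container-dependent estimation has a real
advantage over pooled estimation. Subjects get log-normal per-container
rate multipliers (log-sd 0.03), and speed/amplitude/tremor multipliers of
their own, so LOSO folds always test unseen parameter combinations. The
rate multipliers are kept small so the per-drink amount noise (CV 0.10,
absolute-error floor ≈ 8%) remains the dominant limit on estimation
accuracy, which is what the estimation-stage recovery checks assume.

**Per-drink variability.** Handling tempo (phase durations 0.6–2.4 s),
sip tilt (±20%), reach amplitude (±40%) and at-the-mouth hover time (a
pause at 70% of sip tilt occupying 10–55% of the Lift and Drop phases,
with a small 5 Hz roll adjustment so the container being positioned is
gyro-distinguishable from the static sip) are all redrawn per drink. These dials exist because the whole-activity
feature vector is otherwise *too* informative in a clean simulation:
scale-free moments such as skewness of `az` directly encode the fraction
of the event spent at sip tilt, and with narrow phase durations the total
event duration is a near-noiseless proxy for sip duration. Real container
handling does not repeat itself that exactly. Even with these dials, on
annotated (ground-truth) boundaries whole-activity features remain close
to sip features in information content; the hierarchical advantage of
spotting appears when boundaries come from the detector, which is
precisely the regime the situation comparison evaluates.

**Randomness.** One root seed drives everything through a documented
fan-out (`derive_seed(seed, subject, trial)`, a 31-bit multiplicative
hash): profiles from one sub-stream, every (subject, trial) from its own,
classifier fits from per-fold sub-seeds. The same seed reproduces a
cohort bit for bit.

**What the generator does not emulate.** No biomechanically validated
kinematics — templates target statistical separability, not realism of
waveform shape; no filling-level effect on wrist inclination; no
free-living background motion; tremor is white, not physiological. A
pipeline that performs well here demonstrates the machinery is correct
and that the claimed performance orderings are recoverable under the
stated generative assumptions; it does not certify performance on human
data.

## Parameter defaults and problem sizes

| Parameter | Default | Why |
|---|---|---|
| Sampling rate | 128 Hz | sensor protocol |
| Moving-average width | 16 samples | noise reduction at 125 ms |
| Detection window / overlap | 160 / 50% | best reported detector configuration |
| Spotting window / overlap | 16 / 50% | best reported spotter configuration |
| Duration threshold | 2 s | minimum time of a complete drink |
| k (detection / spotting k-NN) | 3 / 11 | best reported values |
| AdaBoost rounds × depth | 30 × 3 | accuracy saturates on the cohort; CART weak learners |
| RF trees | 100 | stable votes at cohort scale |
| Spotter training cap | 12 000 windows/fold | gesture windows are abundant (~45 000/fold); a seeded subsample keeps fits tractable without measurable accuracy loss |
| SVR cost / epsilon | library defaults (1 / 0.1) | kernels are the specified choice; constants recorded in the run manifest |

The default cohort produces roughly 9 000–12 000 detection windows per
fold; all evaluation utilities run the full 20-fold LOSO at these sizes.

## Known limitations

* The Nadaraya–Watson estimator in 89 dimensions is dominated by its
  nearest neighbours (the bandwidth shift keeps it numerically stable but
  cannot beat the curse of dimensionality); it is included for
  completeness of the model comparison, not as a recommended choice.
* Fragment revision is defined on the original run structure; for
  pathological alternating sequences (`D,O,D,O,...`) any one-pass rule is
  ambiguous, and ours resolves them deterministically but arbitrarily.
* `class::knn` breaks exact distance ties randomly; with continuous
  features ties have probability zero, but bitwise determinism of the
  k-NN path is not guaranteed the way it is for the seeded ensembles.
* Event-level matching is greedy by overlap; a detector that merges two
  drinks into one event credits only one of them.
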