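# fluidintake

Hierarchical fluid-intake monitoring from a single wrist-worn inertial
sensor, for researchers in wearable human-activity recognition and digital
health who need a tested, reusable reference pipeline: drinking-activity
detection, sip-gesture spotting, and intake-amount estimation in grams,
plus a synthetic cohort generator so every stage runs end to end without
access to human study data.

## The method

The input is a six-channel stream — tri-axial acceleration (±16 G) and
angular velocity (±2000 deg/s) at 128 Hz — from the dominant wrist, with
interval annotations at the activity and gesture level. The pipeline has
four stages:

1. **Pre-processing.** A trailing 16-sample moving average smooths each
   channel; sliding windows segment the stream (160 samples / 50% overlap
   for detection, 16 / 50% for spotting).
2. **Drinking detection.** Eight statistics (mean, sd, variance, max, min,
   range, kurtosis, skewness) over eleven axes — the six channels, the
   norms ‖a‖ and ‖ω‖, and the planar magnitudes a<sub>xy</sub>,
   a<sub>yz</sub>, a<sub>xz</sub> — give an 88-dimensional window feature
   vector, classified Drinking/Other by one of six models (AdaBoost over
   CART trees is the default; decision tree, random forest, naive Bayes,
   k-NN with k = 3, linear SVM). Rule-based modification then revises
   one- and two-window fragments that disagree with identical neighbours
   and deletes detected events shorter than 2 s.
3. **Gesture spotting.** Inside each detected event, a five-class
   classifier (random forest by default, k = 11 for k-NN) labels 16-sample
   windows as Fetch / Lift / Sip / Drop / Release, with the same fragment
   revision; maximal Sip runs become sip intervals.
4. **Amount estimation.** The 88 statistics of the sip segment plus the
   sip duration (feature 89) feed a regression model — linear,
   Nadaraya–Watson Gaussian kernel, or eps-SVR with linear / cubic /
   RBF kernel — either pooled over containers (container-independent) or
   per known container type (can, bottle, handleless mug, handled mug).

Evaluation is leave-one-subject-out throughout, with window-level
sensitivity / precision / specificity / accuracy for detection,
per-gesture one-vs-rest metrics for spotting, and MPE / MAPE
(mean signed / absolute percentage error) for amounts. The hierarchical
comparison contrasts situation (1), regression on the whole detected
drinking event, against situation (2), regression on the spotted sip.

The synthetic cohort emulates a scripted protocol: 20 subjects × 5 trials
× 9 activities (phone call, combing, eating with hands, eating with a
spoon, and four drinks from different containers) — 900 activities, with
gesture-level annotation of every drink, per-drink amounts generated as
`sip_rate[container] × sip_duration × (1 + ε)`, and container fill
tracked across trials (refill before trial 4). See the vignette
(`vignettes/fluid-intake-monitoring.Rmd`) for the signal model and every
design decision.

## Worked example

```r
library(fluidintake)

# a small cohort: 3 subjects x 2 trials
ds <- generate_cohort(protocol_script(n_subjects = 3, trials = 2), seed = 11)
ds
#> <intake_dataset> 6 recordings, 3 subjects, 24 drinks

# full hierarchical LOSO evaluation
report <- run_hierarchical_eval(ds, eval_config(seed = 11))
report
#> <hier_eval_report>
#> Detection (window level, pooled over LOSO folds):
#>   sensitivity precision specificity accuracy
#> 1       94.34     97.09       97.91    96.39
#> Gesture spotting (overall):
#> sensitivity   precision
#>       94.57       94.96
#> Amount estimation:
#>        situation       scope   MPE  MAPE  n
#> 1 whole_activity independent -8.18 49.17 24
#> 2 whole_activity   dependent -4.28 39.79 24
#> 3    sip_gesture independent  2.64 56.79 24
#> 4    sip_gesture   dependent -1.78 35.22 24
#> Drinks: 24, matched 24, missed 0, false alarms 5, fallback 0
```

Reading the output: even with only two training subjects per fold the
detector finds all 24 drinks (window-level accuracy 96%), gesture
spotting is reliable (~95%), and the amount regressions carry 35–57%
MAPE at this tiny cohort size — estimation needs training drinks, and
the numbers tighten substantially at the default 20-subject scale
(detection accuracy ≈ 99%, container-dependent sip MAPE ≈ 13%, see the
reproduction section). Each drink's estimate, its container and whether
sip spotting fell back to whole-event features are in `report$amounts`.

Individual stages are exposed directly:

```r
rec  <- ds$recordings[["S01/T1"]]
sm   <- moving_average(rec, 16)
segs <- segment(sm, window_spec(160, 0.5), ds$activity_tracks[["S01/T1"]])
X    <- window_feature_matrix(sm, segs)       # n_windows x 88
dim(X)
#> [1] 120  88
```

A thin command-line wrapper ships in `inst/cli/fluidintake.R`
(`simulate` and `run-all` subcommands over a JSON config).

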