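---
title: "Detecting physical activity from CGM and heart-rate streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting physical activity from CGM and heart-rate streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exdetect)
```

## The problem

People with type 1 diabetes who exercise without adjusting their insulin
risk hypoglycemia: muscular glucose uptake rises during activity while the
injected insulin keeps acting. An automated detector that notices ongoing
physical activity from signals the patient already wears — a continuous
glucose monitor (CGM) reporting interstitial glucose every 5 minutes, and
optionally a heart-rate (HR) band — could warn, annotate records, or feed
an insulin-dosing controller. The physiological signature is subtle on the
glucose side: the exercise-induced decline appears with a lag of roughly
10–15 minutes and is confounded by meals, sensor noise and slow glycemic
wander, whereas heart rate responds within a couple of minutes.

`exdetect` implements this detection task as a tested pipeline: a seeded
synthetic cohort generator, readers for the two source-data dialects the
task is usually studied on, the cleaning rules that produce labeled
5-minute series, sliding-window feature extraction, a 14-classifier suite,
and ROC/AUC evaluation over five train/test protocols including
cross-cohort generalization. The central scientific claim the pipeline
exists to examine is that adding two heart-rate features to the glucose
dynamics raises detection AUC from mediocre to clinically acceptable
(above 0.8).

## Record model and cleaning rules

Everything downstream operates on one record shape: `[date, time, BG in
mg/dL, optional integer HR in bpm, exercise 0/1]` at a nominal 5-minute
interval, in chronological order, with body weight held separately per
subject (`subject_series`).

Two source dialects feed this model:

* **Ohio-style XML archives** — per-subject documents with
  `glucose_level`, `exercise` and `basis_heart_rate` event sections and a
  `weight` attribute. Glucose is natively mg/dL; exercise is
  *self-reported* with a start time, duration in minutes and a 1–10
  intensity. A registration is labeled 1 when it falls inside a reported
  episode, using the half-open interval `[start, start + duration)` — the
  half-open choice is ours; it makes boundary registrations unambiguous.
  Reports with intensity below 2 are not treated as exercise
  (`min_intensity` in `cleaning_config()`).
* **D1namo-style CSV folders** — glucose registrations in mmol/L plus a
  1 Hz wearable summary with HR and an activity level. HR and activity are
  averaged over each inter-registration interval `(t_i, t_{i+1}]` (~300
  samples at 1 Hz) and assigned to the closing registration; the label is
  1 when the mean activity level *strictly exceeds* 0.2, the wearable's
  mild-activity bar. Glucose is converted to mg/dL at ingest
  (× 18.0182) so that features are comparable across dialects; the
  conversion can be disabled (`unit_convert = FALSE`).

Analysis operates on **midnight-to-midnight day blocks** that (a) cover at
least `min_day_coverage` (default 0.9) of the day's nominal grid with no
gap wider than `max_gap` (default 7.5 min = 1.5 × the interval), (b)
contain at least one exercise-positive registration, and (c) when
`require_hr` is set, have HR at every registration. Days with reported
exercise but inadequate CGM are dropped, as are days without any reported
exercise — self-reporting is unreliable enough that an unlabeled day
cannot be trusted as negative. The exact coverage criterion is not fixed
by the studies this design follows, so both thresholds are configurable;
tightening either can only remove blocks (a property the tests assert).

## Window features: FS1 and FS2

Features are computed over a sliding window of 15 consecutive
registrations — 70 minutes end to end — split into three 5-record "mini
windows". With `bg(0..14)` the window's glucose (oldest first) and
`Δt = 5` min:

* end-to-end difference `d = bg(14) − bg(0)` and speed `v = d / (14Δt)`;
* step differences `dp(i) = bg(i+1) − bg(i)` and speeds
  `vp(i) = dp(i)/Δt`, `i = 0..13`;
* mini-window differences `dpp(i) = bg(5i+4) − bg(5i)` and speeds
  `vpp(i) = dpp(i)/(4Δt)`, `i = 0..2`;
* accelerations `ap(i) = (bg(i+2) − bg(i)) / (2Δt)²`, `i = 0..12`.

`ap`'s denominator is the *square* of the two-step time span, exactly as
the feature is defined in the literature this follows, even though that
mixes a first difference with a squared time — fidelity over dimensional
tidiness. The features are deliberately redundant (`Σ dp = d`;
`dpp` telescopes from `dp`; `vp·Δt = dp`): different learners are
sensitive to different presentations of the same dynamics. The tests
assert these identities exactly.

**FS1** is `[w, d, dp(0..13), dpp(0..2), v, vp(0..13), vpp(0..2),
ap(0..12)]` — 50 features including body weight `w`. **FS2** appends the
HR at the newest registration and its last step difference, `hr` and
`hrp = hr(14) − hr(13)` — 52 features. Two design points are ours because
the source material leaves them open: the row label is taken from the
*newest* window record (the window is the causal history of the moment
being classified — no future leakage, which a test asserts by perturbing
future records), and `hr`/`hrp` are evaluated at the newest registration.

A model needs 15 registrations before its first complete window, i.e. 75
minutes from stream initiation. Earlier rows are emitted with all
window-derived features zero (weight kept) — the "database loading"
convention — and the same zero-padding is applied to any row whose window
would span a cleaned-out gap; `warmup = "drop"` removes such rows instead,
since whether training matrices should contain the padded rows is not
settled (the default keeps them). Windows never cross day-block
boundaries, so padding recurs at each block start.

## The classifier suite

`classifier_registry()` returns 14 fixed configurations behind one
fit/score/predict contract, in the order used by all result tables:
ridge-penalized logistic regression (max 1000 iterations), AdaBoost with
50 trees, KNN with k = 5, an unlimited-depth decision tree, Gaussian naive
Bayes, SVMs with rbf / sigmoid / polynomial (degree 3, 5, 10) kernels,
a 100-tree random forest, and MLPs with four hidden layers
(100, 150, 100, 50) and logistic / ReLU / tanh activations trained for at
most 1000 iterations. The settings are fixed a priori — no hyperparameter
search happens in this package.

Standard learners are delegated: `glmnet` (ridge logistic, λ = 1/n
matching a unit-cost L2 penalty), `class::knn`, `rpart` (`cp = 0` to
leave the depth effectively unlimited), `e1071` for naive Bayes and the
SVMs (libsvm; `gamma = 1/(p·Var(X))`, `coef0 = 0`), and `randomForest`.
Two learners are implemented in-package because no installed package
provides them: discrete AdaBoost (SAMME) over depth-1 `rpart` stumps, and
the four-hidden-layer MLP (full-batch Adam, learning rate 1e-3, Glorot
initialization, gradient-norm clipping, early stopping when the loss
improves by less than 1e-4 for 10 consecutive epochs). One caveat: libsvm
exposes a convergence tolerance rather than an iteration cap, so the
SVMs' "1000 iterations" setting cannot be mapped exactly — they run to
convergence.

Numerical conventions of the contract: every learner's score is mapped to
(0, 1) with higher = more likely exercise (probabilities where available,
vote fractions for KNN/forest, logistic-mapped margins for AdaBoost and
the SVMs), and `predict_classifier()` thresholds the score at 0.5, so
score and prediction can never disagree. Two training options are exposed
and recorded in the model metadata because the source studies are silent
on both: seeded undersampling of the majority class to 1:1 (default on —
exercise-positive registrations are a small minority, and the
near-symmetric sensitivity/specificity in published results suggests some
balancing) and feature standardization (default off — published SVM/MLP
results are consistent with unscaled inputs). Zero-variance features
under naive Bayes get a floor of 1e-9 on the class SD to keep densities
finite.

## Evaluation protocols

`compute_metrics()` evaluates ACC, TPR, TNR, PPV, FPR and F1 exactly from
the confusion counts; any zero-denominator ratio is reported as 0 and
flagged (when TP + FP = 0, F1 is flagged too — the direct formula
evaluates to 0 but the harmonic form is undefined). `roc_curve()` sweeps
the distinct score values with ties grouped and integrates AUC by
trapezoid; the tests verify it against brute-force pairwise concordance
and against `pROC`. `youden_threshold()` offers the ROC-derived operating
point as an alternative to the default 0.5.

Five protocols mirror the study designs this pipeline supports: feature
set FS1 or FS2 on a single cohort with an internal 75/25 split (use-cases
1–4), and train-on-cohort-A / test-on-cohort-B in full (use-case 5). The
default split is *chronological per subject* — the earliest 75% of each
subject's rows train — because adjacent windows share 14 of 15 records
and a random row split would leak near-duplicates across the boundary. A
seeded stratified random split is retained as an option since published
75/25 statements rarely specify the mode. All subjects are pooled into
one matrix per use-case.

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so the package carries a
generator (`sim_config()`, `generate_cohort()`) whose defaults define the
study conditions used throughout the tests and the acceptance script:

| component | default | rationale |
|---|---|---|
| CGM | 5-min grid, noise SD 5 mg/dL | typical consumer CGM error |
| baseline glucose | 140 ± 20 mg/dL across subjects | T1DM running above euglycemia |
| glycemic wander | mean-reverting, rate 0.005/min, SD 0.25 mg/dL/√min | slow drift between meals |
| meals | 3/day, +40–80 mg/dL, 45-min rise, 120-min decay | main benign confounder |
| episodes | 1/day, 10–90 min, intensity 3–8, minute-quantized | self-reports carry minute resolution |
| glucose response | −0.3 mg/dL/min per intensity unit after a 12-min lag; exponential recovery (τ = 45 min) | a 40-min intensity-5 session drops ≈ 40–60 mg/dL |
| heart rate | rest 70 ± 6 bpm, +9 bpm per intensity unit, first-order onset τ = 2 min, noise SD 3 bpm | HR leads glucose by design |
| activity channel | rest 0.05, +0.12 per intensity unit, noise SD 0.02 | makes the 0.2 threshold meaningful |
| imperfections | 10% of episodes unreported; 0.2 CGM dropouts/day of 15–120 min | the self-report problem; sensor gaps |

The glucose response is piecewise linear with exponential recovery — the
literature gives delay and persistence only qualitatively, so the
simplest monotone controllable shape was chosen. Unreported episodes
still move glucose and heart rate but carry no label, which is exactly
the annotation problem cross-cohort evaluation probes. Each component
(episodes, meals, drift, each noise channel, gaps) draws from its own
seeded substream, so changing one knob leaves the others' draws intact —
ceteris-paribus tests depend on this. Everything is deterministic given
`(seed, subject_index)`.

What the generator does **not** emulate: insulin pharmacokinetics and
meal–bolus interplay, circadian glucose structure, sensor drift or
compression artifacts, HR artifacts such as cardiac autonomic neuropathy,
or correlated dropout. Passing tests on this cohort therefore show that
the pipeline's mechanics are correct and that the HR-over-CGM advantage
holds when the signal is present as modeled — they do not certify
performance on real patients.

## Problem sizes and numerical choices

The test suite and the acceptance script run the headline comparison on
10 seeded cohorts of 10 subjects × 7 days (≈ 9–11k feature rows each) and
the cross-dialect protocol on an 8-subject training cohort against a
4-subject 1 Hz test cohort — sizes chosen so the full suite completes in
a couple of minutes on one core while keeping several hundred positive
registrations per run. Window spacing is checked to 1e-6 min; glucose has
a physical floor of 20 mg/dL (never reached at realistic settings);
aggregated HR is rounded to integer bpm to match the record structure;
D1namo-style glucose is serialized in mmol/L at one decimal, introducing
a quantization of at most ~0.9 mg/dL after conversion, as the sensors
themselves report.

## Known limitations

* The two in-package learners are faithful to their families but not
  bit-compatible with any particular external implementation (SAMME vote
  weights; full-batch rather than minibatch Adam).
* The SVM iteration cap is approximated by libsvm's convergence criterion.
* Day-block retention thresholds are configurable but their defaults are
  this package's choice; real archives' implicit cleaning rules may
  differ.
* `aggregate_highrate()` assigns interval means to the closing
  registration; other alignment conventions would shift FS2's `hr`
  features by one interval.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 4, days_per_subject = 7, seed = 1)
cohort <- generate_cohort(cfg, highrate = FALSE)
blocks <- unlist(
  lapply(cohort, function(s) extract_day_blocks(s$series, cleaning_config())),
  recursive = FALSE
)
res <- run_use_case(use_case_config(3, "fs2", seed = 1), blocks)
print(res)

# the headline comparison over repeated cohorts
study <- compare_feature_sets(seeds = 1:5, models = "RandomForest",
  n_subjects = 4, days_per_subject = 7)
aggregate(cbind(auc_fs1, auc_fs2) ~ model, study, median)
```
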