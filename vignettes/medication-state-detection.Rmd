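---
title: "Detecting the medication On/Off state from knee-worn accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the medication On/Off state from knee-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstate)
```

## The problem and the data model

Parkinson's disease patients on dopaminergic therapy fluctuate between an
"On" state, in which medication suppresses motor symptoms, and an "Off"
state with parkinsonian gait: reduced cadence and step length, higher
stride-to-stride variability, and frequently a 4–6 Hz rest/postural tremor.
`gaitstate` classifies 10-second windows of bilateral knee-worn tri-axial
accelerometer signal (32 Hz sampling, ±8 g range, acceleration in g) into
these two states.

A *course* is one ~3–4 minute walk by one subject in one state; a complete
study-shaped cohort has four recordings per subject (left/right knee ×
On/Off). The unit of classification is the 320-sample *fold* (10 s at
32 Hz). Misclassification in either direction has a distinct clinical cost:
calling a true On "Off" invites an unnecessary dose reduction, calling a
true Off "On" an unnecessary increase — so the evaluation reports
class-symmetric (macro) averages alongside sensitivity and specificity.

## Preprocessing

Each axis is filtered with a Butterworth low-pass, default order 4 and
cutoff 15 Hz (`filter_spec()`). Two points deserve emphasis:

* **The 15 Hz cutoff sits at 0.94 × Nyquist for 32 Hz data**, so the
  default filter removes only a thin band below 16 Hz. It is kept exactly
  as specified for fidelity to the acquisition protocol the package models;
  `filter_spec()` emits an advisory when cutoff/Nyquist > 0.9, and both the
  order and cutoff are plain arguments.
* **Zero-phase (forward–backward) filtering is the default.** Feature
  extraction is offline, and a causal pass would delay gait events by a
  frequency-dependent lag that biases stride timing. A `causal` mode is
  retained for parity experiments; its single-pass magnitude response is
  the analytic Butterworth curve `(1 + (f/fc)^(2·order))^(-1/2)`, which the
  test suite verifies at f/fc ∈ {0.13, 0.5, 1.0} within 2% (the bilinear
  prewarp makes the response exact at the cutoff).

Courses are filtered whole, then windowed — filtering after segmentation
would add per-window edge transients for no benefit. Windows are
contiguous, non-overlapping, in temporal order. A final partial fold is
retained iff it has at least half a fold (160 samples); this round-half-up
rule is the unique simple threshold consistent with every per-course window
count in the packaged reference bookkeeping table (e.g. a 250-sample
remainder is kept, a 97-sample one dropped). Unequal left/right stream
lengths are truncated to the shorter stream with a warning; no resampling
or reorientation is performed.

## Statistical features

Ten descriptors per knee per window, computed on the per-sample Euclidean
magnitude √(ax²+ay²+az²) — one value per scalar feature per knee matches
the 16-per-knee feature naming — except the signal magnitude area, whose
formula explicitly uses the three axes: SMA = (1/n)Σ(|X|+|Y|+|Z|).
Conventions that matter for reproducibility:

* standard deviation uses the **population** divisor n;
* MAD is the raw `median(|x − median(x)|)`, no consistency factor;
* energy is the mean squared magnitude (units g²);
* **IQR uses Tukey hinges** — the median of each half with the overall
  median included in both halves for odd n — so that on x = (1,2,3,4,5)
  the quartiles are 2 and 4 and IQR = 2;
* skewness is the adjusted Fisher–Pearson coefficient
  `n/((n−1)(n−2)) Σ((x−X̄)/s)³` with the *sample* s. The third power is
  essential: without it the expression is dimensionally inconsistent and
  identically near zero;
* kurtosis is population **excess** kurtosis `m₄/m₂² − 3` (the fourth
  moment over the squared second; a squared-standard-deviation denominator
  would not be dimensionless);
* a zero-variance window has skewness and kurtosis defined as 0, not NaN,
  and windows of 2–3 samples emit 0 for both with a note — the feature
  matrix must stay dense for all four classifier families.

Partial windows use their actual length as n throughout. All ten formulas
are verified against an independent direct-evaluation oracle to 1e-10
relative on 1,000 random windows, plus scale/translation equivariance
checks.

## Spatiotemporal gait features

The six gait parameters (step/stride length, time, velocity) require gait
events. The event detector (`detect_strikes()`) is this package's explicit
construction — the quantities themselves are standard, but no detector
algorithm is prescribed by the protocol the package models — and all of its
thresholds are exposed:

1. **Stride period** from the autocorrelation of the window's magnitude
   series within `period_band` (default 0.4–3.2 s, covering cadences of
   roughly 40–300 steps/min at two steps per stride). The period is the
   *smallest* autocorrelation local maximum reaching half the band maximum:
   a periodic signal has comparable peaks at harmonics of the true lag, and
   taking the global maximum can land on the two-stride lag. A window whose
   best in-band autocorrelation is below `min_autocorr = 0.25` is declared
   aperiodic (white noise at n = 320 stays below ~0.12 with high
   probability, walking autocorrelation is typically > 0.5).
2. **Candidate peaks**: local maxima above mean + 0.5·sd of the window.
3. **Refractory suppression**: among candidates closer than half the
   estimated stride period, the larger peak wins.

Detected events are one leg's heel strikes, so inter-event intervals are
stride times; step time is half the stride time under the symmetric-gait
convention used throughout (each knee is processed independently; the
bilateral alternation is not fused across sensors, and no asymmetry
indices are produced). Step length comes from the inverted-pendulum model
`L = 2√(2·l·h − h²)` with pendulum (leg) length l (default 0.9 m,
overridable per subject since no demographic leg lengths are distributed)
and h the per-stride vertical excursion: the vertical axis (config-declared,
default axis 3) is linearly detrended per stride (removing the gravity
offset and slow drift), converted g → m/s², integrated to velocity, the
velocity detrended (zeroing integration drift), integrated to position, and
h taken as the position peak-to-peak range, clipped at h ≤ l. Stride length
is twice the step length and velocities are length/time ratios, so the
identities `stride = 2·step` and `v = L/t` hold exactly by construction on
every non-flagged window.

Windows with fewer than two retained events emit **zeros with a quality
flag** (`flag_left`/`flag_right` columns), never missing values.

## Classifiers and hyperparameters

Four families with fixed reference defaults (`classifier_spec()`):

| family | defaults | fitted with |
|---|---|---|
| random_forest | 500 trees, Gini, max depth 8, min leaf 10 | `ranger` |
| svm | RBF, C = 1, γ = 1/n_features, tol = 1e-3 | `e1071::svm` |
| knn | k = 50, uniform weights, Euclidean | `class::knn` |
| naive_bayes | Gaussian | `e1071::naiveBayes` |

Mapping notes: `ranger` is used for the forest because it exposes
`max.depth` directly; `min_samples_split = 8` is recorded but non-binding
(a minimum leaf of 10 already forbids splits below 20 samples). The kNN
`leaf_size` and `algorithm` settings are search-tree implementation details
with no effect on exact Euclidean predictions. SVM probability scores use
internally cross-validated Platt scaling (a held-out logistic map of the
decision values); kNN scores are the neighbourhood vote share; "On" is the
positive class everywhere.

**Feature selection.** `rfe()` removes the lowest-ranked feature one at a
time until `n_keep` remain (default: the "Used" count of the packaged mask
for that family, so recomputed masks are size-comparable). The forest ranks
by impurity importance; the RBF SVM, kNN and naive Bayes expose no
coefficient/importance notion, so they fall back to a univariate |Welch t|
ranking, announced via a message. The packaged per-family masks ship in
`inst/extdata/feature_masks.tsv`.

**Hyperparameter search.** `smbo_optimize()` maximises a user objective by
sequential model-based optimization: a Latin-hypercube initial design
(n_init ≥ 2, default 5), then rounds of fitting a Gaussian-process
surrogate — Matérn 5/2 kernel, signal variance = var(y), isotropic
lengthscale set by the median-distance heuristic, 1e-6 relative nugget —
and evaluating the candidate maximising the closed-form expected
improvement `EI = (μ−f*)Φ(z) + σφ(z)`, `z = (μ−f*)/σ`, over a fresh
uniform pool of 1024 points (pool-based acquisition avoids an inner-loop
optimiser and keeps the search deterministic given the seed). Failing
objective evaluations are recorded at the worst observed score and the
search continues. The surrogate budget is a package default, not a tuned
quantity; 30 evaluations recover a 1-D quadratic argmax within 5% in the
test suite.

## Evaluation

The confusion bookkeeping follows the per-subject report convention: the
true-On row holds `tp` (On→On) and `fp` (On→Off), the true-Off row `fn`
(Off→On) and `tn` (Off→Off); hence `tp + fp` is the subject's On-window
count and `fn + tn` the Off-window count. `confusion_metrics()` derives
accuracy, sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV, macro
(unweighted two-class) recall/precision/F1 — macro is the default because
the near-balanced window design makes macro ≈ micro, but the choice is
explicit — and the diagnostic odds ratio with the Haldane–Anscombe +0.5
correction on all cells whenever any cell is zero. ROC-AUC is the
rank-based (Wilcoxon) estimator with ties at ½ and a 1000-resample
bootstrap 95% CI (the CI method is this package's choice). Both the 70:30
split (floor(0.7·n) subjects to train, 14/6 at n = 20) and
leave-one-subject-out folds partition **subjects**, and every fold asserts
that the held-out subject is absent from its training roster.

The packaged reference bookkeeping table
(`reference_confusion_table()`) stores the 20 per-subject rows only; the
report's Total row is always recomputed as column sums, which keeps the
report arithmetically self-consistent.

## The synthetic cohort

`simulate_course()` generates, per knee: a 1 g gravity baseline on the
vertical axis plus a train of Ricker (Gaussian-windowed biphasic) impulses
of FWHM ≈ 0.1 stride period at that leg's strike times — smooth,
band-limited, and peaked enough for the detector — with left/right strikes
offset by half a stride; anterior–posterior and mediolateral axes are
scaled (0.5/0.3), slightly lagged copies with independent noise; optional
tremor sinusoid and white noise complete the model. Stride intervals are
jittered multiplicatively with the configured CV. The packaged On/Off
contrast (`on_default_config()`/`off_default_config()`) is: On at 100
steps/min, 1 g impulses, 2% timing CV, no tremor; Off at −20% cadence,
−40% impulse amplitude, 3× jitter, plus a 0.25 g tremor at 5 Hz — the
qualitative signature of unmedicated parkinsonian gait. `simulate_cohort()`
adds subject-level random effects (cadence offset SD 6 steps/min,
log-normal amplitude multiplier SD 0.1) applied to both courses, and draws
each course's duration uniformly from 185–235 s so window counts vary as
in real recordings.

What the simulator does **not** emulate: freezing-of-gait or shuffling
episodes, turning, postural transitions, sensor misalignment, orientation
drift, or the within-course nonstationarity of real patients (warm-up and
fatigue). Consequently, a perfect LOSO score on the packaged contrast
demonstrates that the pipeline's plumbing, features and validation are
sound — not that clinical discrimination of this accuracy is attainable;
the packaged contrast is deliberately well separated, and the
null-separation control (identical On/Off generators, which must classify
at chance) guards against information leaking through the pipeline. For
that control the acceptance band is |accuracy − 0.5| < 0.2, set from the
course-level clustering of windows (40 courses ⇒ SE ≈ 0.079, ~2.5 SE),
not from the window count.

## Problem sizes and numerical choices

The shipped validation runs use 20-subject cohorts at 185–235 s per course
(~840 windows), six cadences for gait recovery at 60 s each, 1,000 random
windows for the feature oracle, and 30 SMBO evaluations — sizes chosen so
the whole suite exercises every advertised property at statistically
meaningful scale on a single CPU. Degenerate inputs are contracts, not
surprises: empty courses yield empty window lists, single-sample windows
error, zero-variance windows produce defined features, event-poor windows
produce flagged zeros, single-class training sets error, and the writer
refuses to produce an empty feature file. Doubles round-trip text I/O
bitwise via 17-significant-digit formatting.

## Known limitations

* The gait-event detector and pendulum integration are a documented
  stand-in for an unpublished prior method; absolute step-length values on
  real data should be calibrated (leg length per subject at minimum).
* The default 15 Hz cutoff barely filters 32 Hz data; treat it as protocol
  fidelity, not as effective denoising.
* Per-knee symmetric-gait conventions double the step metrics rather than
  fusing bilateral timing; asymmetric gaits violate the
  `stride = 2 × step` identity in reality even though the package enforces
  it by construction.
* The GP surrogate uses fixed heuristic kernel hyperparameters; for search
  spaces beyond a few dimensions a marginal-likelihood fit would be
  preferable.
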