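---
title: "Hierarchical gesture and grasp-force classification from enveloped sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical gesture and grasp-force classification from enveloped sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgh)
```

## The problem

Pattern-recognition myoelectric control classifies surface EMG (sEMG) from
the residual forearm of a transradial amputee into intended hand/wrist
motions. Commercial active sensors deliver an *enveloped* signal — already
rectified and low-pass filtered, hence nonnegative — so classification can
operate directly on amplitude patterns across a bracelet of six sensors.
`emgh` implements a hierarchical strategy that controls two things at once:

* a first-stage classifier picks one of **seven gestures** — rest,
  spherical, platform, point, tip, supination, pronation;
* if, and only if, the gesture is one of the two grasps (spherical or
  tip), a second-stage classifier simultaneously assigns one of **three
  relative force levels** (low, medium, high) evaluated on the same
  analysis window.

That yields 11 distinct motion classes (5 non-grasp gestures + 2 grasps
× 3 levels), each mapped to a prosthesis command: hand or wrist actuation
at a PWM duty cycle of 25/50/75 % for the grasp force levels
(corresponding to roughly 7.5/15/30 N of measured grip force) and a fixed
50 % for the non-grasp movements.

## Signal model and the synthetic subject

No subject recordings ship with the package. The `synthgen` layer
generates sessions with the statistical structure the acquisition
protocol assumes, so every downstream stage is testable end to end:

* **Protocol.** Seven gestures held for 3 s at 1 kHz, six repetitions
  each; the two grasps repeated at all three force levels
  (66 recordings per session); three 3-s dynamometer repetitions per
  force level for calibration; 5-s continuous streams for real-time
  trials, three per motion class (33 trials).
* **Envelope model.** Each channel of a hold is
  `activation[gesture, channel] × force_gain[level] × rep_factor ×
  noise(t)`, with 200 ms linear onset/offset ramps, clipped at zero.
  The noise is multiplicative and log-normal, smoothed by a 50 ms
  moving-average kernel and rescaled so its marginal coefficient of
  variation equals `noise_cv` exactly — mimicking the slow amplitude
  wander of an already-enveloped sensor output rather than raw EMG
  interference patterns.
* **Activation template.** Each gesture is dominated by two or three of
  the six channels (distinct muscle synergies); rest is a low uniform
  baseline. Amplitudes are arbitrary sensor units.

### Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| `noise_cv` | 0.2 | envelope amplitude wander of ~20 % is typical of steady submaximal contractions |
| `rep_jitter` | 0.08 | repetition-to-repetition amplitude drift within a single session is small but nonzero |
| `force_gain` | 0.5 / 1.0 / 1.9 | self-selected low/medium/high grips sit near 25/50/95 % of maximum voluntary contraction, and envelope amplitude scales roughly linearly with force |
| ramps | 200 ms | rise time of a deliberate contraction onset |

The gains and jitter were fixed once, at design time, from this %MVC
reading; with them the generated classes satisfy the package's
separability contract (between-gesture centroid gaps of at least three
within-class standard deviations at default noise), which is what makes
the offline performance checks meaningful. Real-time streams are
generated without onset ramps: a trial captures an already-maintained
contraction.

**What the generator does *not* emulate:** raw-EMG interference
structure, motor-unit firing statistics, electrode shift, fatigue,
crosstalk drift, or the idiosyncrasies of individual residual limbs.
Passing tests on synthetic sessions therefore demonstrate correctness of
the pipeline and achievable separability under the stated noise model —
not expected performance on any particular amputee.

## Feature extraction

Windows of 150 ms with 50 ms overlap between consecutive windows (step
100 ms) are cut per contiguous class block; a 4,800-sample class block
yields 47 windows. Five time-domain descriptors are computed per channel
(30 columns, fixed order):

* **EMAV** — enhanced mean absolute value,
  $\frac{1}{N}\sum_i |x_i|^{p(i)}$ with $p(i) = 0.75$ for
  $0.2N \le i \le 0.8N$ and $0.5$ otherwise (1-based, boundaries
  inclusive), de-emphasising window edges;
* **EWL** — enhanced wavelength, $\sum_{i=2}^{N}|x_i - x_{i-1}|^{p(i)}$,
  same exponent rule;
* **SSC** — slope-sign-change count with a dead-zone threshold
  (default 0, meaning a strictly positive product
  $(x_i - x_{i-1})(x_i - x_{i+1})$ is required);
* **RMS** and **VAR** (mean-subtracted, $N-1$ denominator).

Conventions deliberately pinned down where the field varies: "overlap of
50 ms" is read as the shared span between consecutive windows (step =
window − overlap = 100 ms), not as a 50 ms step; VAR subtracts the window
mean rather than assuming zero-mean EMG (the envelope is nonnegative, so
the zero-mean convention would be wrong here); both the SSC dead zone and
the exponent rule are configurable.

Columns are z-scored with mean/sd fitted on training rows only and stored
inside the model, so any later window — including real-time ones — is
standardised identically. Constant columns keep sd = 1 and pass through
centred.

## Classifiers

All three algorithms are trained one-vs-all and share the decision rule.

**LR / NLR.** Class membership probability
$P(c \mid x) = 1/(1 + e^{-(\theta^\top \tilde x + \theta_0)})$, where
$\tilde x$ is the input for LR (degree 1) and its degree-2 polynomial
expansion for NLR — linear terms, pairwise products, squares
($d + d(d+1)/2$ dimensions; 495 for the 30 features). Training minimises
L2-penalised cross-entropy (penalty `l2/(2n)·‖θ‖²`, bias excluded) by
full-batch gradient descent from zero initialisation with a step-halving
safeguard, so the accepted loss sequence is non-increasing. Defaults:
learning rate 0.1 on standardised inputs, at most 5,000 iterations,
relative-loss tolerance 1e-7, `l2 = 1e-4`.

After fitting, each class's decision threshold is chosen from a grid
(0.05–0.95, step 0.05) to maximise that class's one-vs-rest F1 on a
stratified 20 % validation carve-out of the training part — never on test
data. Ties break toward 0.5, then toward the lower threshold. At
prediction time, among classes whose probability reaches their threshold
the most probable wins; if none qualifies, the globally most probable
class is the fallback; exact ties resolve to the earlier class code.
One-vs-all probabilities are independent binary posteriors and are never
renormalised.

**LDA.** Closed-form discriminants under the equal-covariance Gaussian
model: $h_\beta(x) = \max_c(\beta_c^\top x + \beta_{0c})$ with
$\beta_c = \Sigma^{-1}\mu_c$, pooled within-class covariance $\Sigma$
stabilised by a ridge of $10^{-6}\,\mathrm{tr}(\Sigma)/d$ on the
diagonal, and empirical class priors. Exactly noise-free training data
(zero within-class scatter) is reported as a calibration error rather
than silently regularised into a near-singular solve.

## The cascade and force calibration

`predict_hierarchical()` evaluates the gesture classifier on a window's
feature vector; only a spherical or tip output triggers the matching
force classifier, on the *same* vector. Force classifiers are trained
exclusively on windows from their own grasp class across all three
levels. "Simultaneous" gesture and force output is implemented as
same-window sequential evaluation — no concurrency is needed for
correctness at a 90 ms decision stride.

Force levels are grounded in newtons by dynamometer calibration. The
default (perceived-force) method averages the plateau mean — central
80 % of each 3-s trace — over repetitions per level; bands follow the
±10 % rule: low `[0.9L, 1.1L]`, medium `[0.9M, 1.1M]`, high from `0.9H`
to the maximum observed force. Non-monotone L < M < H is an error;
overlapping low/medium bands a warning. The alternative
maximum-force-fraction method (30/60/90 % of max) is provided as
`method1_thresholds()`. Thresholds label calibration data; they are not
consulted at inference time.

## Evaluation

**Offline.** Each of the three problems (gesture, spherical force, tip
force) is split 70/30 stratified per class — with feature extraction the
split is applied to the analysis windows (windows are never computed
across a split boundary); without it, to raw sample rows — then trained
and scored on the held-out part: accuracy, per-class F1 (0 when
precision + recall is 0), macro-F1, confusion matrix. Algorithms are
compared with a two-sided Mann–Whitney U test: exact permutation
enumeration when the smaller sample has ≤ 8 observations (ties handled by
enumerating midranks), otherwise the tie-corrected normal approximation
with continuity correction; Bonferroni gating at α/m (0.05/3 ≈ 0.0167 for
three pairwise comparisons).

**Simulated real time.** A trained hierarchy is driven over 5-s synthetic
streams: every 90 ms the most recent 150 ms window is classified, giving
⌊(5000 − 150)/90⌋ + 1 = 54 decisions per trial; three trials for each of
the 11 motion classes. *Online accuracy* is the percentage of decision
ticks predicting the target class exactly (for grasps, gesture **and**
level must match; every tick from the first full window counts — no
transient exclusion, since the streams model maintained contractions).
A trial is *completed* when the target is predicted for a cumulative
1.0 s (≥ 12 ticks at defaults); the motion completion rate is the
percentage of completed trials. The completion rule is configurable
(`complete_s`): cumulative-time is our operationalisation of motion
completion, chosen over consecutive-tick variants because a 90 ms stride
makes single-tick dropouts common and clinically irrelevant.

## Numerical and design choices

* Stratified split rounds each class's training share to nearest, ties
  toward training; deterministic under a seed (all library seeding is
  scoped and restores the caller's RNG state).
* Gradient descent diverging to a non-finite loss raises an error
  advising a smaller learning rate; a step that would increase the loss
  is halved instead of taken.
* The 33,600-row session matrix takes the central 800 steady-state
  samples of each 3-s repetition (discarding the 200 ms ramps); each
  grasp gesture draws two repetitions per force level so the gesture
  classifier sees all contraction intensities.
* Model JSON carries full-precision parameters, the normaliser and a
  format-version tag; LR/NLR/LDA share one envelope distinguished by a
  `family` field.

## Problem sizes used by the test suite

The shipped tests run the full 66-recording default session (33,600-row
matrix, 329 feature windows) for the offline checks, a reduced
2-repetition/1.2-s session for CLI round trips and noise-sensitivity
checks, 200 randomised instances for metric-counting oracles, and 33
simulated trials of 1.5–5 s for the real-time protocol — sizes chosen so
the whole suite completes in about a minute on one core.

## Known limitations

* Synthetic envelopes are stationary within a hold; no electrode shift,
  fatigue or limb-position effects, so reported synthetic scores are an
  upper bound on field performance.
* Offline splits operate on windows from the same repetitions (as the
  underlying two-way split protocol does), not on leave-repetition-out
  folds; between-session generalisation is out of scope.
* NLR supports degree 2 only; higher-degree expansions would need a
  different optimiser to stay practical.
* Raw-mode (no feature extraction) hierarchy feeds per-channel window
  means to classifiers trained on individual samples — adequate for the
  envelope signal, but the extracted mode is the intended configuration.
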