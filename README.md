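# emgh — hierarchical gesture and grasp-force classification from enveloped sEMG

`emgh` is an R toolkit for pattern-recognition myoelectric prosthesis
control research. It implements a hierarchical classification strategy
that decodes, from six channels of enveloped surface EMG sampled at
1 kHz, **seven hand/wrist gestures** (rest, spherical, platform, point,
tip, supination, pronation) and — whenever the decoded gesture is one of
the two grasps (spherical, tip) — **three relative grasp-force levels**
(low, medium, high) on the same analysis window, for 11 motion classes in
total. Predictions map to prosthesis commands: hand/wrist actuation at
PWM duty cycles of 25/50/75 % for the force levels (≈ 7.5/15/30 N of
grip force) and 50 % for non-grasp movements.

The pipeline covers:

* **Feature extraction** — sliding 150 ms windows with 50 ms overlap;
  five time-domain descriptors per channel: enhanced mean absolute value
  (EMAV, the mean of `|x_i|^p(i)` with a positional exponent
  `p(i) ∈ {0.5, 0.75}`), enhanced wavelength (EWL), slope sign change
  (SSC), RMS and variance — 30 features per window.
* **Classifiers** — one-vs-all logistic regression
  `P(c|x) = 1 / (1 + exp(−(θᵀx̃ + θ₀)))` trained by
  full-batch gradient descent, linear (LR, `x̃ = x`) or with degree-2
  polynomial expansion (NLR); closed-form pooled-covariance LDA
  `h(x) = argmax_c (β_cᵀx + β_c0)`. Per-class decision
  thresholds are selected on a validation carve-out to maximise
  one-vs-rest F1.
* **Hierarchy** — the gesture→force cascade, dynamometer-based force
  threshold calibration (±10 % bands around the low/medium/high plateau
  means), and prosthesis command mapping.
* **Evaluation** — stratified 70/30 offline experiments (accuracy,
  per-class F1, confusion matrices, Mann–Whitney U with Bonferroni
  gating) and a simulated real-time loop producing a decision every
  90 ms over 5-s trials, scored by online accuracy and motion completion
  rate (MCR).
* **Synthetic data** — a protocol-faithful generator of enveloped-EMG
  sessions, dynamometer traces and real-time streams, so the entire
  pipeline runs and is tested without subject recordings.

## Worked example

```r
library(emgh)

profile <- subject_profile(seed = 7)      # synthetic subject
session <- generate_session(profile)      # 66 labelled 3-s holds

# Offline experiment: LR with feature extraction, 70/30 split
reports <- run_offline_experiment(session, algorithm = "lr", fe = TRUE,
                                  seed = 1)
reports$gesture
#> <offline_report> LR with FE: accuracy 1.000, macro-F1 1.000
#>   platform      point  pronation       rest  spherical supination        tip
#>          1          1          1          1          1          1          1

# Train the full hierarchy and simulate the real-time protocol
h  <- train_hierarchical(session, "lr")
rt <- run_realtime_experiment(h, profile)   # 11 classes x 3 x 5-s trials
as.data.frame(rt)[c(6, 10), c("label", "online_accuracy", "mcr")]
#>            label online_accuracy mcr
#> 6  spherical/low          100.00 100
#> 10    tip/medium           91.36 100

# Calibrate force thresholds from synthetic dynamometer traces
cal <- unlist(lapply(force_levels(), function(l)
  generate_force_calibration(profile, "spherical", l)), recursive = FALSE)
calibrate_thresholds(cal, "spherical")
#> <force_thresholds> spherical: L/M/H = 10.4/21.3/40 N, f_max = 73.5 N
#>   low    [9.34, 11.4] N
#>   medium [19.2, 23.4] N
#>   high   [36, 73.5] N

map_to_command("spherical", "high")
#> <prosthesis_command> hand close_power @ PWM 75% (~30 N)
```

The offline report says the seven gestures are perfectly separated on the
held-out 30 % of windows for this synthetic subject; in the real-time
simulation, 91.4 % of the 90-ms decision ticks during `tip/medium` trials
predicted exactly that gesture-and-level pair, and every trial
accumulated ≥ 1 s of correct decisions (MCR 100 %). The calibration
output shows the three force bands in newtons that label the grasp
training data.

## Command line

A thin wrapper (`inst/exec/emgh`) drives the same pipeline from a shell:

```sh
emgh generate  --config run.json          # synthesise a session
emgh calibrate --config run.json          # force thresholds
emgh train     --config run.json          # fit the hierarchy
emgh evaluate  --config run.json          # offline report
emgh stream    --config run.json          # simulated real-time report
```

All commands accept `--seed`, `--algorithm lr|nlr|lda`, `--fe/--no-fe`,
`--data-dir`, `--out`; every output directory gets a manifest with the
config hash and seed, and identical config + seed reproduces reports
byte for byte.

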