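---
title: "Modelling Tabata energy expenditure from accelerometer and heart-rate streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Tabata energy expenditure from accelerometer and heart-rate streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabataEE)
```

## The problem

Tabata training is a high-intensity interval protocol: eight stages of a
20-second all-out bout followed by a 10-second standing rest, four minutes in
total. Estimating its energy expenditure (EE) from wearable sensors is hard
for exactly the reasons that make the protocol effective: movement is
intense, non-periodic and heterogeneous across limbs, heart rate never
reaches a steady state, and the 10-second rests spend energy (excess
post-exercise oxygen consumption) while the accelerometer reads essentially
zero. A single linear model on accelerometer counts — the classic approach
for walking and running — carries little information during the intervals
and misses the HR-mediated component during the bouts.

`tabataEE` implements a complete modelling pipeline for this setting:

1. a **synthetic cohort generator** emulating the sensor streams of a
   laboratory Tabata test (30-Hz tri-axial counts at four wear sites,
   per-second heart rate, per-10-s reference EE in kcal);
2. **window feature construction** — vector-magnitude (VM) statistics, HR
   aggregates and anthropometrics on the protocol's 10-s windows;
3. **variable screening and model fitting** — Pearson-correlation ranking,
   p-value stepwise linear regression (LR), and a from-scratch
   single-hidden-layer backpropagation network (BPNN) with momentum and an
   adaptive learning rate;
4. a **validation battery** — subject-level train/test split, Bland-Altman
   limits of agreement, MAPE, RMSE, and per-stage error decomposition.

## Window structure and features

`build_window_plan()` partitions the session into contiguous, half-open,
protocol-aligned 10-s windows, labelled exercise or interval: the classic
protocol gives 24 windows per subject in the pattern (E, E, I) × 8.

For every window the per-sample vector magnitude
$\mathrm{VM}_i = \sqrt{x_i^2 + y_i^2 + z_i^2}$ is computed from the
tri-axial counts and summarised by its within-window sum (the VM predictor
used in regression) and ten statistics: mean, SD, the covariance with the
previous window's VM samples, min, max and the 10/25/50/75/90th
percentiles. Percentiles use linear interpolation between order statistics
(R's default type-7 convention), stated explicitly so every value is exactly
testable. The first window's adjacent covariance is defined as 0 — it has no
predecessor, and this keeps one feature row per window. Together with the
window-mean heart rate and the subject's height, weight and sex code
(female 0 / male 1), these form the 14 inputs of the network models,
matching their 14-6-1 and 14-10-1 architectures.

Regression works from two period-specific candidate sets. Exercise windows:
the window VM sum at each of the four wear sites, the window-mean exercise
HR, and the anthropometrics. Interval windows: nine right-ankle VM/HR
aggregates of the surrounding stage (VM during 0–10 s, 10–20 s, 0–20 s of
the bout and the whole stage; HR over the same segments, the whole stage,
and the interval itself) plus the anthropometrics — during a standing rest
the accelerometer is silent, so the stage's recent history is the signal.

## The synthetic cohort generator

No public dataset accompanies this modelling problem, so the generator *is*
the study population; every statistical claim the tests make is a claim
about these conditions. Its defaults describe a young-adult cohort
(age 21.0 ± 2.4 y, height 1.67 ± 0.075 m, weight 59.6 ± 8.3 kg, body fat
18.5 ± 5.5 %, 51 % female; all truncated normal, BMI recomputed from the
drawn height and weight) performing the classic protocol at genuinely high
intensity: exercise HR averaging 165.5 ± 5.4 bpm, observed maxima near
183 bpm (≈90 % of the age-predicted maximum), and roughly 8–9 METs during
bouts.

Design choices where the problem is silent:

* **Counts.** Per-axis, per-sample counts are truncated normal at a
  site-specific exercise scale (ankle strongest, hip weakest; CV 0.35),
  multiplied by a subject-level vigour term. That term has a shared
  component (SD 0.10) and a per-site component (SD 0.12): limbs covary in
  how hard a subject moves but not perfectly, so the four sites' VM sums
  are correlated yet statistically distinguishable — without the per-site
  component the design matrix is near-collinear and no selection procedure
  could identify which limb drives EE. Interval counts sit at a near-zero
  truncated-normal level; setting `interval_level = 0` reproduces the
  idealised "VM is zero while standing" case exactly.
* **Heart rate.** A first-order on/off model: exponential approach to a
  per-stage bout target (time constant 15 s) and exponential decay toward a
  recovery asymptote during intervals (20 s), with a small upward drift of
  the bout target across stages (3 bpm/stage, emulating cardiovascular
  drift) and per-second Gaussian noise (SD 2 bpm). Because 20-s bouts and
  10-s rests never reach steady state, the raw trajectory's mean would sit
  well below its asymptote; the trajectory is therefore shifted so that
  each subject's *exercise-second mean* equals their drawn plateau. This
  makes the plateau parameter interpretable as the subject's mean exercise
  HR — the quantity summarised in intensity reports — while preserving the
  on/off dynamics. The trajectory is capped at a subject-level maximum
  (183.4 ± 7.1 bpm).
* **Energy expenditure.** Per-window EE is a linear function of the window
  VM sum (right ankle), window-mean HR and body weight, with
  period-specific coefficients, plus Gaussian noise (SD 0.15 kcal/window),
  floored at 0. The default coefficients were chosen once to land the
  physiology where a classic Tabata test sits: ≈1.45 kcal/10 s
  (≈8.8 METs) during bouts and ≈1.2 kcal/10 s during rests at the
  population-mean anthropometrics, which puts the noise floor of any
  correctly specified model's MAPE near 9–10 %, inside the 10–15 % band
  conventionally called a reasonable EE prediction error.
* **Nonlinearity.** An optional term
  `gain * tanh(z_hr * z_vm + 0.5 * z_hr^2)` is added to exercise windows,
  where `z_hr` and `z_vm` are the centred/scaled window HR and VM. It is an
  HR-by-movement interaction — precisely the structure an additive linear
  candidate set cannot express but a small network can — and it saturates,
  so extreme draws cannot push a window's EE to the physiologically
  impossible zero floor. The default gain is 0 (purely linear world); the
  comparative experiments in the test suite use gain 0.4.

What the generator does **not** emulate: biomechanics of the four exercise
movements, device-specific count filtering, HR-monitor dropouts,
inter-window EE autocorrelation beyond what HR kinetics induce, or any
population other than healthy young adults. Tests passing under these
conditions show the *procedure* is implemented correctly and behaves as
expected where its assumptions hold — they are not evidence about any real
cohort.

## Stepwise regression

`stepwise_fit()` is forward selection with backward elimination driven by
partial-F p-values: repeatedly add the excluded candidate with the smallest
p-value below `p_enter` (0.05), then drop any included term whose p-value
has risen above `p_remove` (0.10). The asymmetric defaults are the common
statistics-package convention and guarantee progress; a cycle guard bounds
the iteration count. Exactly duplicated candidates are aliased in the
refit and can never enter twice. If nothing is admissible the model is
intercept-only and flagged. The published fixed-coefficient equations for
both periods are available as `published_lr()` and evaluated exactly as
printed; note that the exercise equation's HR coefficient (0.193 kcal per
bpm per 10 s) implies implausibly large per-window EE at typical exercise
HR — likely a units or typesetting artefact in the original table — and is
deliberately left uncorrected.

## The backpropagation network

A single hidden layer with logistic-sigmoid (`logsig`) activations at both
the hidden and output layer, trained by full-batch gradient descent on the
scaled mean-squared error with a momentum term (0.9) and an adaptive
learning rate: starting from 0.05, after each epoch the step is kept and
the rate multiplied by 1.05 if the error did not grow by more than 4 %;
otherwise the step is discarded, the rate multiplied by 0.7 and the
momentum buffer reset. Training stops at a scaled-MSE goal of 0.001 or
5000 epochs. The adaptive constants (1.05 / 0.7 / 1.04) are the canonical
defaults of this scheme, fixed here so runs are reproducible.

Because the output unit is a sigmoid, targets must live strictly inside
(0, 1): EE targets are min-max scaled to [0.1, 0.9] — the headroom keeps
early training away from the saturated tails where gradients vanish — and
inverted at prediction; inputs are min-max scaled to [0, 1] (a constant
column is given an artificial unit range centred on its value, so it scales
to 0.5 and contributes nothing). Weights and biases initialise uniformly on
[−0.5, 0.5] from a seed. The analytic backpropagation gradient is exposed
(`bpnn_gradient()`) and is verified against central finite differences in
the test suite — the module's master correctness oracle.

The hidden-layer size heuristic takes
`round(sqrt(n_input + n_output))` as a base and tries the base plus
0–11 nodes, clipped to [4, 15]; for 14 inputs and 1 output that is exactly
4–15. `hidden_node_search()` trains one freshly seeded network per
candidate and compares RMSE on a held-out quarter of the rows, breaking
ties toward the smaller (simpler) network. The pipeline defaults to the
fixed sizes 6 (exercise) and 10 (interval) — the published architectures —
with the search available by option, since the search multiplies training
cost by twelve.

## Validation battery

Splitting is always at the *subject* level — window-level splitting would
leak a subject's own windows into their evaluation. The training share is
`round(0.75 · n)` (half-up); an explicit `n_test` override exists because a
15-of-45 validation group (as sometimes reported) corresponds to a 2:1
split and cannot be reproduced by any rounding of 3:1 — both behaviours are
supported rather than silently reconciled.

MAPE is `100/n · Σ|measured − predicted|/denominator`. The default
denominator is the measured value (the standard convention); an
`"as-printed"` option divides by the predicted value instead, matching the
error formula as typeset in the source material once its symbol definitions
are read literally. Bland-Altman limits use the sample SD (n − 1) of the
differences and count points lying exactly on a limit as within — the
degenerate perfect-prediction case then reports 100 % coverage, as it
should. The per-stage decomposition reports each stage's MAPE and the
count of stages above 15 %. The MAPE standard error is the SD of
per-subject MAPEs divided by √(number of subjects), so it reflects
between-subject variation rather than window count.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit seed; `run_pipeline()`
  derives all stage seeds from one global seed, so a single integer
  reproduces the cohort, the split, the initial weights and the report.
  Seeding is done with `withr::with_seed()`, leaving the caller's RNG
  state untouched.
* Truncated-normal draws use vectorised rejection; an SD of zero
  degenerates to the mean, which makes "all SDs zero" an exact,
  deterministic fixture for tests.
* `logsig` saturates cleanly at 0/1 for arguments beyond ±500; training
  aborts with a diagnostic if a gradient ever becomes non-finite.
* Model JSON is written with 17 significant digits, so a serialised
  network round-trips bit-exactly.
* Tie-breaks are documented and deterministic: correlation ranking breaks
  |r| ties alphabetically; the hidden-node search breaks RMSE ties toward
  the smaller network.

## Problem sizes used in the test suite

The suite validates the statistical claims at sizes a desk run supports,
chosen as the smallest cohorts at which each property is comfortably
powered: coefficient recovery uses 100 cohorts of 30 subjects (the
cohort-scale of the emulated study); the LR-versus-BPNN comparison uses 10
cohorts of 30 subjects with nonlinearity gain 0.4 and default noise, where
the network's advantage is judged on the seed-averaged overall MAPE;
Bland-Altman coverage uses 10⁵ simulated pairs. Unit fixtures are built in
code at run time — no data files ship with the package.

## Known limitations

* The generator's EE model shares its functional family with the fitted
  models (by design, for identifiability); real reference EE from indirect
  calorimetry is smoother in time and noisier between devices.
* The BPNN is a faithful period implementation — batch gradient descent
  with momentum and adaptive rate — not a modern optimiser; on small
  cohorts it can lose to LR when the world is exactly linear, which the
  comparative tests deliberately do not ask it to win.
* The interval candidate set assumes the classic 20-s bout / 10-s window
  structure; other protocols get window features and exercise candidates
  but not the stage-aggregate interval preset.
* Published-equation predictions are exact transcriptions; they are not
  corrected for the suspected unit inconsistency noted above, so their
  absolute values should not be compared against the generator's kcal
  scale.
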