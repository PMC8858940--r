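# tabataEE

Energy-expenditure (EE) modelling for classic Tabata training — eight
stages of 20 s all-out exercise and 10 s standing rest — from the two
signals cheap wearables provide: tri-axial accelerometer counts and heart
rate. The package is aimed at exercise physiologists and wearable-sensor
researchers who want a fully reproducible, testable implementation of the
combined accelerometer + heart-rate (ACC-HR) modelling procedure for
high-intensity interval training, including the comparison between a
stepwise linear regression and a small backpropagation neural network.

## What it implements

For each non-overlapping 10-s window the per-sample **vector magnitude**
of the counts,

    VM = Σᵢ √(xᵢ² + yᵢ² + zᵢ²),

is summarised (sum, mean, SD, adjacent-window covariance, min, max, and the
10/25/50/75/90th percentiles) and joined with the window-mean heart rate
and the subject's anthropometrics. Two period-specific predictors of
kcal/window are then fitted on a subject-level 3:1 train/test split:

* **Stepwise linear regression** — forward selection with backward
  elimination on partial-F p-values (enter 0.05, remove 0.10), run on the
  pre-selected exercise-period candidates (per-site window VM, exercise HR,
  anthropometrics) and interval-period candidates (stage VM/HR aggregates,
  interval HR, anthropometrics). The published fixed-coefficient equations
  (`EE_exe = 0.000044·VM + 0.193·HR + 0.23·BW − 3.05`;
  `EE_int = 0.000011·VM₃₀ + 0.0116·HR₀₋₁₀ + 0.030·BW − 1.99`) are available
  verbatim via `published_lr()`.
* **Backpropagation network** — a from-scratch 14-input, single hidden
  layer, logistic-sigmoid network (the 14-6-1 / 14-10-1 architectures),
  trained by batch gradient descent with momentum 0.9 and an adaptive
  learning rate (initial 0.05, ×1.05 on accepted epochs, ×0.7 on rejected
  ones), targets min-max scaled to [0.1, 0.9], up to 5000 epochs or a
  scaled-MSE goal of 0.001. Hidden-node counts can be searched over the
  heuristic range `round(√(nᵢ + nₒ)) + 0..11` clipped to 4–15 by held-out
  RMSE.

Agreement is assessed with Bland-Altman limits (mean difference ±1.96 SD),
MAPE, RMSE and a per-stage MAPE decomposition. Because no public dataset
accompanies the problem, a seeded **synthetic cohort generator** emulates
the study population (30-Hz counts at four wear sites, on/off heart-rate
kinetics averaging ≈165 bpm during bouts, ≈8–9 METs, near-zero interval
counts); the methods vignette documents every generative assumption.

## Worked example

```r
library(tabataEE)

result <- run_pipeline(pipeline_config(
  sim = sim_config(nonlin_gain = 0.4),  # HR x movement interaction on
  n_subjects = 30, seed = 1             # top of the linear EE model
))
result
#> <ee_pipeline_result> 30 subjects (23 train / 7 test)
#> <ee_validation_report> 7 test subjects, 168 predictions/model (MAPE denominator: measured)
#>   bpnn MAPE 11.84% (SE 1.86), RMSE 0.222 kcal, r^2 0.390
#>   lr   MAPE 12.26% (SE 2.33), RMSE 0.226 kcal, r^2 0.370

tidy(result$models$lr_exercise)
#> # A tibble: 6 x 3
#>   term             estimate   p_value
#>   <chr>               <dbl>     <dbl>
#> 1 (Intercept)    -2.38      NA
#> 2 hr_exercise     0.00893    1.58e-20
#> 3 weight          0.0131     1.87e-21
#> 4 vm_right_ankle  0.0000389  3.79e- 8
#> 5 body_fat        0.00991    2.64e- 5
#> 6 height          0.657      7.40e- 4
```

The report reads: on the 7 held-out subjects (24 windows each), the
network's mean absolute percentage error is 11.8 % of the measured
kcal/window against 12.3 % for the stepwise regression — both inside the
10–15 % band conventionally considered a reasonable EE prediction error,
with the network ahead because the generating model contains an
HR-by-movement interaction the additive regression cannot express. The
tidied exercise-period equation shows stepwise selection keeping the three
generative drivers (heart rate, body weight, ankle VM) — plus two
anthropometric proxies that earn their p < 0.05 on this particular cohort —
every retained term significant at the 0.05 entry rule. `autoplot()` on a `bland_altman()` result, `plot_stage_mape()`
and `plot_predicted_measured()` draw the standard figures.

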