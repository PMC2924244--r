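# multirate

Multi-rate state-space modeling of anterograde interference in
force-field motor adaptation.

When people adapt reaching movements to a velocity-dependent force
field (Task A) and are then switched to the opposite field (Task B),
learning Task B is slowed. `multirate` is an analysis package for that
phenomenon, built around a two-process state-space learner: on each
trial the motor error `e(n) = f(n) − x(n)` (disturbance minus net
output, `x = x_f + x_s`) updates a fast and a slow adaptive process,

    x_f(n+1) = A_f x_f(n) + B_f e(n)
    x_s(n+1) = A_s x_s(n) + B_s e(n),      B_f > B_s,  A_s > A_f.

The slow process accumulates a bias toward Task A that persists when
the net output has already returned to baseline, and that residual bias
slows Task B learning. Interference is quantified as the percent
reduction of the rectified opposite-learning curve relative to initial
learning over the first 25 trials after the zero-crossing:

    AI = 1 − L̄_opposite / L̄_initial.

The package provides, as plain R functions:

* trial-by-trial simulation of the two-process model (and a
  single-process control) over arbitrary schedules of field,
  error-clamp and null trials (`simulate_two_state()`,
  `simulate_single_process()`, `steady_state()`);
* the study's AB schedules with interleaved error-clamp probes
  (`standard_groups()`, `build_schedule()`);
* trace-level measurement: minimum-jerk reach kinematics, ideal
  compensatory force, baseline subtraction, the regression adaptation
  index with four slope estimators, mid-movement force, and sign
  standardization (`adaptation_index()`, `mid_movement_force()`,
  `orient()`);
* learning-curve operations: interpolation, smoothing, zero-crossing
  alignment, rectification, the interference metric, final learning,
  and the alternative onset-aligned and time-constant metrics;
* constrained multi-start model fitting and subject-level bootstrap
  confidence intervals (`fit_two_state()`, `bootstrap_ci()`), three
  R² variants, ANOVA and t-test wrappers;
* a synthetic-cohort generator (`generate_cohort()`) producing complete
  per-subject force-trace datasets, so the full pipeline
  (`run_analysis()`) runs end to end with no external data.

## Worked example

```r
library(multirate)

params <- default_two_state_params()
pred <- predict_ai(params, standard_groups())
pred[, c("group", "taskA_trials", "taskA_strength", "ai")]
#>        group taskA_trials taskA_strength        ai
#> 1     full13           13            1.0 0.1335202
#> 2     full41           41            1.0 0.3426978
#> 3    full112          112            1.0 0.5602883
#> 4    full230          230            1.0 0.6204271
#> 5    full369          369            1.0 0.6268557
#> 6 reduced230          230            0.5 0.3340168

mean(pred$ai[2:5])
#> [1] 0.5375672
```

Interference builds with Task A duration and saturates: the three
longest groups sit within 0.07 of each other while the 13-trial group
shows barely a fifth of the asymptotic level. The four longest
full-strength groups average 0.54 — the model's near-asymptotic
interference level. The half-strength 230-trial group is predicted at
0.33, *more* than the full-strength 13-trial group despite a lower
final learning level (its ceiling on the full-strength convention is
0.5), which is why the level of final learning cannot by itself explain
interference.

A full synthetic-cohort analysis — 58 subjects in six groups, force
traces, measurement, alignment, metrics, fits and bootstrap intervals:

```r
report <- run_analysis(cohort_config(seed = 42))
report$group_summary[, c("group", "model_ai", "cohort_ai",
                         "ai_ci_lower", "ai_ci_upper")]
report$hypothesis$reduced_higher_ai_despite_lower_final
#> [1] TRUE
```

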