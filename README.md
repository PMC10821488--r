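# wheelmotion

Detection of **active (self-propelled) versus passive (attendant-pushed)
wheelchair use** from chair-mounted inertial sensors.

For rehabilitation clinicians and movement scientists monitoring manual
wheelchair users (e.g. after stroke or lower-limb amputation), the
question is rarely just *how much* the chair moved but *who* moved it —
self-propulsion is physical activity, being pushed is not. `wheelmotion`
implements the full analysis chain for answering that question from a
single 6-axis IMU (50 Hz gyroscope + accelerometer) on one rear-wheel
hub, optionally joined by a second IMU on the frame:

1. **Kinematics** — gyro bias correction from periods of no motion
   (< 5°/s); forward speed `v = ω_roll · r` corrected to chair center by
   `v − Ω · track/2`; yaw rate Ω either from the frame gyro's vertical
   axis (configuration **S2**, the *full model*) or recovered from the
   spinning wheel sensor alone (**S1**, the *wheel model*) via a
   complementary filter tracking the wheel angle θ from gyro integration
   fused with the accelerometer's gravity direction, then
   `Ω = g_y sin θ + g_z cos θ`; zero-phase 6 Hz low-pass differentiation;
   dead-reckoned 2D path.
2. **Segmentation** — maximal runs of `|v| > 0.1 m/s` lasting ≥ 2 s,
   labelled active/passive by majority overlap with timed annotations.
3. **Features** — a fixed 56-predictor vector per segment:
   {FFT amplitude spectrum of speed, linear acceleration, roll/pitch/yaw
   angular velocity and acceleration} × {median, SD, skewness, excess
   kurtosis} (8 × 4 derived) plus the raw gyro channels and their
   derivatives from the configuration's own sensor (6 × 4 raw); greedy
   pruning of predictors with pairwise |r| > 0.7.
4. **Classification** — stratified 80/20 splits (label × diagnosis),
   10-fold cross-validated selection among logistic regression, SVM,
   random forest, naive Bayes and gradient-boosted trees by F1
   (positive class = active), repeated over 25 random splits;
   gain-based feature importance normalised to sum 1.
5. **Simulator** — a physics-based generator of ground-truth trials
   (9 m slow / normal / slalom / stop-go bouts plus free roaming, four
   propulsion styles including one-hand-one-foot and backward driving)
   rendered into raw wheel and frame IMU streams with realistic noise
   and bias, so the entire chain is validated without any recordings.

## Worked example

```r
library(wheelmotion)

# simulate a small cohort: 6 participants, two protocol runs + free roam each
cohort <- generate_cohort(6, seed = 11)

# wheel-only (S1) features for every labelled movement segment
fm <- cohort_feature_matrix(cohort, variant = "S1")
nrow(fm)                         # segments entering the model
length(prune_correlated(fm))     # predictors surviving |r| > 0.7 pruning

# 5-split benchmark
rep <- run_benchmark(fm, n_splits = 5, seed = 19)
print(rep)
```

```
#> Propulsion-type benchmark (S1, 5 splits, 34 predictors retained)
#>   Accuracy   Precision  Recall     F1
#>   0.924      0.956      0.900      0.927
#>   chosen families: random_forest (5)
```

Read: on 230 simulated segments, the wheel-only model classifies
held-out propulsion bouts with mean F1 ≈ 0.93 across splits; a tree
ensemble wins cross-validation on every split. `feature_importance(fm)`
then shows which aggregates carry the signal — led by the roll-axis
angular-velocity median, whose correlation with active use is negative
(attendants push faster), followed by acceleration and speed-spectrum
aggregates — each row annotated with its correlation sign.

The full pipeline — simulate, reconstruct, segment, featurise, benchmark
both sensor configurations, write artifacts — is one call:

```r
res <- run_end_to_end(list(participants = 24, seed = 1, n_splits = 25,
                           out_dir = "run1"))
```

A thin command-line front end with the same stages is installed at
`inst/cli/wheelmotion.R` (`simulate`, `validate`, `convert`,
`kinematics`, `segment`, `features`, `benchmark`, `run`).

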