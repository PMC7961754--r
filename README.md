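# insolegait

Gait analysis and sarcopenia screening from bilateral foot-mounted
inertial sensors (smart insoles), in R.

Sarcopenia — age-related muscle loss — shows up in gait: lower walking
speed, longer stance, reduced single support on the weaker side, and
left-right asymmetry. `insolegait` turns raw 12-channel insole recordings
(3-axis accelerometer + 3-axis gyroscope per foot, 100 Hz) into a
subject-level screening decision:

* **Seven-event segmentation.** Rule-based detectors for heel strike
  (HS), opposite toe-off (oTO), heel rise (HR), opposite heel strike
  (oHS), toe-off (TO), feet adjacent (FA) and tibia vertical (TV). HS is
  the largest first difference of walking-direction acceleration within
  10 samples of its pre-stance minimum; TO is the per-cycle gyro-y
  maximum; HR is the first gyro-y sample ≥ 0.25 rad/s after mid-stance
  quiescence; FA is the swing zero crossing of acc-x; TV is where
  re-integrated forward velocity returns to zero. Strides segment into
  stance/swing or the seven Whittle phases.
* **Gait features.** The 23 spatiotemporal parameters (cadence;
  stance/swing/single-/double-support phase % and time per side; step
  times; stride length by ZUPT-EKF strap-down integration; speed; |R−L|
  asymmetries), and 10 descriptive statistics per channel per phase
  (12 × 2 × 10 = 240 or 12 × 7 × 10 = 840 columns), plus 100-point
  spline-resampled stride tensors for sequence models.
* **Shapley-value feature selection.** Welch t-test screen to 50
  features, gradient-boosted trees (binary logistic, 20 rounds, depth 15,
  gamma 0.009, subsample 0.98), path-conditional TreeSHAP attribution
  φᵢ — with an exact 2ⁿ subset-enumeration oracle of
  φᵢ(v) = Σ_{S⊆N∖{i}} |S|!(n−|S|−1)!/n! · (v(S∪{i}) − v(S)) for
  verification — keeping at most the top 20 features with mean |φ| ≥
  0.002.
* **Classification.** Linear/RBF SVM (γ = 1, C = 5), random forest (50
  trees), a 2×20-unit tanh MLP, a 1D CNN (64 filters, kernel 8, pool
  4/4) and a stacked BiLSTM (64/32 units, lr 5e-4, dropout 0.2), all
  evaluated leave-one-subject-out per group with fold-internal
  standardization and selection.
* **Synthetic cohort generator.** Clinical insole recordings of
  sarcopenic gait are private, so the package ships a bilateral gait
  simulator with exact ground-truth event annotations and planted group
  effects; every stage is validated against it.

## Worked example

```r
library(insolegait)

cohort <- simulate_cohort(cohort_spec(seed = 42))   # 10 + 10 subjects, 4 cycles
det <- detect_gait_events(cohort$subjects$S01$recording)
det
#> <gait_detection> left 4 / right 4 strides, 0 dropped

spatiotemporal_params(det$left, det$right,
                      recording = cohort$subjects$S01$recording)
#>   cadence stance_phase_r single_support_phase_r stride_length speed stance_time_drl
#>       100         62.083                 32.708          1.16 0.966           0.063
```

Subject S01 walks at 0.97 m/s with 62% stance, 32.7% right single support
and a 63 ms stance-time asymmetry — the planted sarcopenic pattern (slow,
long stance, reduced right single support, asymmetric).

```r
features <- build_feature_table(cohort, "seven")    # 80 strides x 840 features
screened <- ttest_prescreen(aggregate_by_subject(features), k = 50)
shap <- shap_values(fit_gbt(screened), screened)
head(tidy(shap), 3)
#>   feature                         importance  rank
#> 1 acc_x_l_mid_stance_skewness           2.15     1
#> 2 acc_x_l_loading_response_ab_sum       0        2
#> 3 acc_x_l_mid_stance_kurtosis           0        3

ev <- loso_evaluate(features, model_spec("svm_linear"), screen_k = 50, top = 20)
ev
#> <loso_eval> svm_linear, 10 folds: accuracy 90.0% (sd 21.1)
```

On this seed a single mid-stance skewness feature of the left
walking-direction acceleration already separates the groups in the
attribution model (the remaining screened features contribute no
additional splits), and the fold-internal pipeline classifies 18 of the
20 held-out subjects correctly. `autoplot(shap)` draws the attribution
summary plot; `autoplot(ev)` the per-fold accuracies.

A command-line front end mirrors the stages:

```sh
exec/gaitpipe simulate --n-per-group 10 --cycles 4 --seed 1 --out data/
exec/gaitpipe detect --left data/N01_left.csv --right data/N01_right.csv --out events.json
exec/gaitpipe run --out run1/        # full pipeline + manifest with file hashes
```

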