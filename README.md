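# gazentropy

Sleep deprivation impairs driving not only by closing drivers' eyes but by
reorganising where and how they look. `gazentropy` is an R package for
analysing eye-tracking recordings from driving studies of sleep deprivation
and time-on-task fatigue. It takes raw 50 Hz gaze samples through the full
chain:

1. **Event detection** — dispersion-threshold (I-DT) fixation detection
   (80 ms / 100 px defaults), blink detection from tracking-loss runs with a
   ≤ 300 ms microsleep filter, and saccade amplitudes between fixation
   centroids.
2. **Gaze entropy** — fixations are discretised onto a spatial grid
   (100 px cells for 5-minute bins, 30 px for 1-minute prediction bins) and
   summarised per time bin as *stationary* entropy
   `H_s = −Σ p(i) log₂ p(i)` (how dispersed gaze is over the occupied
   cells) and *transition* entropy
   `H_t = −Σ p(i) Σ_{j≠i} p(j|i) log₂ p(j|i)` (how unpredictable the
   scanpath is, self-transitions excluded), each normalised by its maximum
   entropy to [0, 1].
3. **Analysis tables** — 5-minute bin tables with last-observation-carried-
   forward imputation of post-termination bins (early terminations are
   condition-caused, not missing at random), and per-driven-minute tables
   with the binary lane-departure outcome.
4. **Models** — paired t-tests, within-subject ANOVA (F = t² on two
   conditions), Poisson rate models with exposure offsets, polynomial mixed
   models for time-on-task drift, Kaplan–Meier survival of driving duration,
   binomial logistic lane-departure prediction, likelihood-ratio tests, and
   ROC evaluation with Youden operating points.
5. **Synthetic data** — a seeded generator of full sessions (50 Hz samples,
   ground-truth events, per-minute lane counts) with known logistic and
   Poisson lane-departure truths, calibrated so detected fixation rate,
   blink rate and saccade amplitude match the study-condition means.

Everything is tidyverse-native: functions take and return tibbles, fitted
objects have `tidy()`/`glance()` methods, and result types have
`autoplot()`/`plot_*()` companions.

## Worked example

```r
library(gazentropy)

params <- gaze_params()                                  # study-condition defaults
study  <- generate_study(params, n_participants = 9, seed = 1)
res    <- run_pipeline(study, pipeline_config(seed = 1), out_dir = "artifacts")

nrow(res$bin_table)
#> [1] 432
```

432 rows is the balanced design: 9 participants × 2 conditions × 24
five-minute bins, complete after LOCF imputation of bins lost to early
terminations. The lane-departure rate contrast and the base prediction
model:

```r
tidy(res$rate_model)
#> # A tibble: 1 × 5
#>   term                    rate_ratio conf_low conf_high  p_value
#> 1 conditionsleep_deprived       2.35     2.04      2.70 1.48e-32

tidy(res$base_model)
#> # A tibble: 3 × 5
#>   term                                odds_ratio conf_low conf_high  p_value
#> 1 conditionsleep_deprived                   4.18    2.70       6.48 1.39e-10
#> 2 driving_min                               1.01    1.01       1.02 1.18e- 7
#> 3 conditionsleep_deprived:driving_min       1.00    0.995      1.01 5.65e- 1

glance(res$roc_base)
#> # A tibble: 1 × 4
#>     auc sensitivity specificity threshold
#> 1 0.713       0.669       0.654     0.305
```

Driving in the sleep-deprived condition more than doubles the lane-departure
rate, the odds of a departure event rise by about 1 % per minute driven, and
the condition + duration model discriminates event minutes at AUC ≈ 0.71.
The survival of driving duration (`autoplot(res$km)`) steps down only in the
sleep-deprived condition, ending at 0.22–0.33 depending on the seed, i.e.
roughly two-thirds of sleep-deprived drives end early.

Entropy itself:

```r
stationary_entropy(c("A", "A", "B", "C"))
#> # A tibble: 1 × 6
#>   H_bits H_max_bits H_norm H_pct n_fixations degenerate
#> 1    1.5       1.58  0.946  94.6           4 FALSE
```

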