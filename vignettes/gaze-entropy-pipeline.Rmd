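---
title: "Gaze entropy and lane-departure prediction: methods"
author: "gazentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze entropy and lane-departure prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazentropy)
library(dplyr)
```

# The problem

Sleep deprivation degrades driving not only through eyelid closure but by
disrupting where and how drivers look. This package implements a complete
analysis pipeline for that question: raw 50 Hz gaze samples from a
head-mounted eye tracker are segmented into fixations, saccades and blinks;
fixation sequences are discretised onto a spatial grid and summarised as
*stationary* and *transition* gaze entropy per time bin; per-bin measures are
assembled into an analysis table together with per-minute lane-departure
counts; and a battery of models quantifies condition effects, time-on-task
drift, driving-duration survival, and per-minute prediction of lane
departures. A calibrated synthetic-session generator with known ground truth
stands in for raw recordings, which are typically not shareable.

# Event detection

Fixations are detected with the classic dispersion-threshold algorithm
(I-DT): a window of consecutive valid samples grows while its dispersion —
`(max x − min x) + (max y − min y)`, the Salvucci–Goldberg definition — stays
within `max_dispersion_px`, and is emitted when it also spans at least
`min_duration_ms`. Defaults are 80 ms and 100 px, the conventional thresholds
for vehicle-mounted scene cameras. The maximum pairwise distance is available
as an alternative dispersion definition, since vendor analysis suites do not
document their exact variant and parity with any particular vendor is not
claimed. Invalid samples terminate an open window, so blinks split
fixations — a deliberately conservative choice given that vendor behaviour is
unknown.

Blinks are maximal runs of invalid samples. A blink's offset is the first
valid sample *after* the run: a run of five invalid samples at 50 Hz spans
100 ms, and ending events at the last invalid sample would bias durations low
by one sample interval. Blinks longer than 300 ms (boundary inclusive:
exactly 300 ms is kept) are excluded from blink statistics as candidate
microsleep epochs and returned separately.

Saccade amplitude is the Euclidean distance between consecutive fixation
centroids scaled by `deg_per_px`. The scene-camera field of view is
tracker-specific and rarely reported; the default 0.05 deg/px corresponds to
a wide-angle scene camera (64° across 1280 px) and is configurable.

# Gaze entropy

Fixation centroids are assigned to square grid cells ("state spaces") by
floor division with half-open intervals; a 100 px grid is used for
condition and time-course analyses in 5-minute bins, and a 30 px grid for
the 1-minute bins of the prediction analysis, where lane keeping depends on
finer spatial structure. Only occupied cells enter the calculations.

**Stationary entropy** is the Shannon entropy of the occupancy distribution,

$$H_s = -\sum_i p(i)\,\log_2 p(i),$$

with $p(i)$ the proportion of the bin's fixations in cell $i$. It is
normalised by $H_{max} = \log_2 k$ over the $k$ occupied cells, so
$H_{norm} \in [0,1]$ measures how evenly gaze is spread over the places it
actually visited; $H_{norm} = 1$ iff occupancy is uniform, and a single
occupied cell gives 0 by convention. `H_pct` is the same value times 100 —
the scale on which entropy enters odds-ratio models "per 1 % increase".

**Transition entropy** is the conditional entropy of first-order Markov
transitions between cells,

$$H_t = -\sum_i p(i) \sum_{j \neq i} p(j \mid i)\,\log_2 p(j \mid i),$$

with three conventions that the notation alone does not pin down:

* $p(j\mid i)$ is the forward transition probability (to $j$ given currently
  in $i$), matching the verbal definition in the scanpath literature;
* self-transitions are removed from the counts and each origin row is
  renormalised over $j \neq i$, so every row is a proper distribution and the
  result is interpretable in bits;
* the outer weight $p(i)$ is the empirical fixation distribution over the
  whole bin (the "stationary distribution of fixation locations"), not the
  invariant vector of the estimated chain.

$H_{max}$ for transitions is $\log_2$ of the number of *distinct observed*
between-cell transitions, so $H_{norm} = 1$ is attainable in finite data; the
alternative reading (all $k(k-1)$ orderable pairs) is available via
`h_max = "possible"`. A scanpath that never changes cell has no valid
transitions and is returned as zero entropy with $H_{max} = 0$ and a
degeneracy flag. Throughout, logarithms are base 2, $0\log 0 \equiv 0$, and
$H_{norm} \equiv 0$ whenever $H_{max} = 0$.

Both normalised values are also reported divided by the bin length in
minutes (`Hs_per_min`, `Ht_per_min`). Reports in this literature are
inconsistent about these units — per-minute summaries of order 0.001–0.01
versus normalised time-course intercepts of order 0.26–0.83 — so the package
emits both conventions and treats `H_norm` as the primary quantity; no claim
of absolute parity with any printed value is made.

# Binning, imputation, and the analysis tables

Sessions are capped at 120 minutes. All measures are organised into
consecutive half-open 5-minute bins; events belong to the bin containing
their onset, so a partition conserves event counts, and the partial final
bin of an early-terminated session normalises rates by the actually driven
length. Early terminations are caused by the sleep-deprived condition
itself — the data are not missing at random — so post-termination bins are
imputed by carrying the last observed bin's values forward (LOCF), flagged,
and never overwrite observed rows. A 9-participant × 2-condition design with
24 bins therefore always yields exactly 432 rows.

The prediction table is different: lane departures are recorded per minute,
so `minute_table()` builds one row per *driven* minute (no imputation — the
prediction models concern real driving, and the imputation device exists
only for the balanced condition-by-time analysis), with ocular summaries,
30 px-grid entropy on the percent scale, and the binary outcome
`lane_departure = (count ≥ 1)`. Counts are retained separately for the
Poisson rate analyses.

# Statistical battery

* `paired_t()` — closed-form paired t-test; zero-variance differences are
  flagged degenerate instead of erroring (identical vectors give
  $t = 0, p = 1$).
* `rm_anova_condition()` — one-way within-subject ANOVA after aggregating to
  participant × condition means (participant as block), giving the
  $F_{[1,n-1]}$ form; with two conditions it equals the squared paired t,
  which the tests verify numerically.
* `poisson_rate_model()` — log-linear Poisson with a log-exposure offset;
  exponentiated coefficients are rate ratios with Wald intervals.
* `polynomial_mixed_fit()` — per condition, a linear mixed model with a raw
  polynomial in driving time and a per-participant random intercept (nine
  subjects cannot support random slopes). The order is selected backward
  from 3: the leading term is dropped while its Satterthwaite p-value is
  ≥ 0.05, mirroring the cubic/quadratic/linear narration conventional in
  this literature; the selection rule behind such narrations is typically
  unstated, so this explicit rule is documented as the package's
  choice. Singular fits fall back one order with a warning. $R^2$ is the
  squared correlation between fitted and observed values.
* `km_curve()` — product-limit estimate of the probability of continuing to
  drive; completions at the cap are censored.
* `logistic_lane_model()` — binomial logistic regression of the per-minute
  outcome; odds ratios with Wald intervals; quasi-separation is detected and
  flagged (no penalised refit is silently substituted).
* `lr_test()` — likelihood-ratio chi-square between nested logistic models
  on identical rows.
* `roc_evaluate()` — empirical ROC with trapezoidal AUC (equal to the
  Mann–Whitney statistic with ties counted ½); the reported operating point
  maximises Youden's J, a rule chosen because reported sensitivity /
  specificity pairs rarely name their threshold rule. Note that "overall
  accuracy" summarised by an AUC is an AUC, not a classification accuracy;
  the package reports it as AUC.

Confidence intervals are Wald on the link scale and exponentiated; no
multiple-testing correction is applied (none is conventional in this design).

# The synthetic-session generator

`generate_session()` builds a session bottom-up with known ground truth.

**Event timeline.** Fixation onsets follow a renewal process: each cycle is
a truncated-lognormal fixation duration, an inter-fixation gap, and — with a
per-cycle probability — a blink of truncated-lognormal duration placed inside
the gap. The gap length is set so the expected cycle matches the target
fixation rate; the blink probability is inflated by the predicted retention
of the 300 ms filter, and the blink `meanlog` is solved (by `uniroot` on the
truncated mean) so the *retained* blinks match the target mean duration.
Default targets are the study-condition means: fixation rate 76.91 / 60.80
per minute, fixation duration 561 / 510 ms, blink rate 39.42 / 52.40 per
minute, blink duration 179.88 / 200.75 ms (rested / sleep-deprived).

**Time-on-task drift.** Fixation- and blink-rate targets are modulated by
condition-specific polynomial time courses of the kind reported for
drowsy-driving studies, evaluated in
5-minute block units — in minutes the sleep-deprived fixation-rate cubic
turns negative well inside a session, so blocks are the only unit consistent
with positive rates. The polynomials act as multiplicative shapes around the
session mean with gain 0.3 and clamping to [0.5, 1.5]: population mean curves
mix between- and within-subject variation, and applying their full amplitude
to every individual session would overstate within-session swing.

**Gaze geometry.** Fixation locations follow a first-order Markov glance
model: a road-ahead Gaussian core at frame centre, and six fixed glance
targets (mirror/instrument-cluster/periphery analogues). From the core the
gaze glances with probability `glance_prob`; from a target it returns with
probability `return_prob` or hops to another target. Sleep deprivation
widens the core (σ 24 → 45 px), spreads the glance distribution from a
mirror-dominated profile to uniform, and halves the return probability —
producing more dispersed occupancy (higher $H_s$) *and* less predictable
transitions (higher $H_t$), the two signatures of drowsy scanning. A single
2D Gaussian cannot do this: with realistic saccade amplitudes it saturates
normalised entropy near 1 with almost no variance, and flattening it raises
$H_{max}$ faster than the conditional entropy, moving $H_t$ the wrong way.
`dispersion_scale` multiplies both σ's and is the single monotone entropy
knob; `glance_prob` was calibrated (0.706 / 0.733) so the mean detected
saccade amplitude at 0.05 deg/px matches 19.16° / 27.77°.

The generator cannot match those amplitude targets and reported
normalised-entropy intercepts of ~0.26 simultaneously — a distribution
concentrated enough for $H_{norm} \approx 0.26$ on a 100 px grid puts almost
all consecutive fixations in neighbouring cells, capping mean amplitude far
below 19°. The calibration contract is therefore the ocular statistics
(fixation rate, blink rate, saccade amplitude within 10 %), with entropy
kept directionally faithful: sleep-deprived > rested, strictly increasing in
`dispersion_scale`.

**Sampling.** Ground-truth events are rasterised at 50 Hz: fixation samples
jitter isotropically (σ 6 px) about the centroid, blink samples are invalid,
and gap samples scatter on a 100–180 px ring around the interpolated
saccade path — gaze estimates during saccades are unreliable in real
trackers, and this placement guarantees the dispersion criterion rejects
them, so detection recovers the generated statistics rather than splitting
events on interpolation artefacts.

**Early termination and lane departures.** Sleep-deprived sessions face a
per-5-minute-block hazard (0.06 after a 30-minute minimum), giving roughly
two-thirds early terminations with a mean drive near 77 minutes; rested
sessions complete. Per-minute lane-departure occurrence follows a logistic
model with known coefficients — condition OR 3.20, OR 1.014 per minute
driven, OR 1.07 per 1 % of realised stationary entropy (30 px grid, centred
at 90 %) — and event minutes carry `1 + Poisson(0.4)` events. Because no
single mechanism can realise both target odds ratios and target
Poisson rate ratios, count-model experiments use the separate
`simulate_lane_counts()` generator (condition rate ratio 3.79, per-block
trend 1.065 in the sleep-deprived condition).

**Study assembly.** `generate_study()` crosses participants with both
conditions, applying per-participant lognormal offsets (rates, durations,
spatial scale; clamped) shared across a participant's sessions, plus a small
per-session "day" jitter (sd 0.08) so paired condition differences carry
realistic within-subject noise. All randomness is seeded; identical seeds
reproduce sessions exactly.

**What the generator does not emulate.** Saccade main-sequence dynamics,
pupil measures, circadian modulation, semantic areas of interest tied to
actual traffic, head movement, and tracker drift. Passing tests demonstrate
that the pipeline's algebra, detection logic, and models are correct and
that parameters injected at realistic magnitudes are recovered — not that
any particular estimate from human recordings is reproduced, since such
recordings are not part of the package.

# Numerical choices and degenerate inputs

* Problem sizes: the test suite exercises 20 full-length (120 min) sessions
  for detection calibration, a 9 × 2 ground-truth study for the design
  checks, 200 replicates at 10× design scale (90 participants) for logistic
  recovery, and 2 × 200,000 simulated minutes for Poisson recovery — sizes
  chosen so Monte-Carlo error is far below the tolerances being checked.
* Entropy oracle agreement is required to 1e-12 bits against a brute-force
  implementation with explicit transition matrices.
* Empty bins yield flagged-missing entropy rows (the caller chooses
  imputation); `stationary_entropy()` on an empty sequence is an error.
* Out-of-frame centroids are clamped to boundary cells with a warning;
  frame extent defaults to 1280 × 960 px with a top-left origin and y
  increasing downward (the usual scene-video convention).
* Ties at the Youden optimum take the first optimal threshold; AUC ties
  count ½.
* Seeds: every generator function takes an explicit seed and restores the
  RNG state on exit (`withr::local_seed`), so library calls never perturb a
  caller's RNG stream.

# A worked example

```{r example, eval = FALSE}
params <- gaze_params()
study <- generate_study(params, n_participants = 9, seed = 1)
res <- run_pipeline(study, pipeline_config(seed = 1), out_dir = "artifacts")

nrow(res$bin_table)          # 432 = 9 participants x 2 conditions x 24 bins
tidy(res$rate_model)         # condition rate ratio for lane departures
glance(res$roc_base)         # AUC / sensitivity / specificity, base model
autoplot(res$km)             # driving-duration survival by condition
plot_timecourse(res$bin_table, "Hs_norm")
```

# Known limitations

* The generator's absolute normalised-entropy levels sit above typically
  reported time-course intercepts (see the units discussion above); conclusions
  should rest on directions, recovery properties, and identities, which is
  what the tests assert.
* LOCF is the only imputation scheme offered; model-based alternatives are
  out of scope.
* With nine subjects the mixed models support only random intercepts;
  condition F statistics on synthetic studies depend strongly on the
  assumed between- and within-subject variance components, for which
  reported condition-mean SDs are only a stand-in.
* Perfectly separated logistic fits are flagged, not penalised; users
  needing Firth-type corrections should fit externally on the exported
  minute table.
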