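---
title: "Methods: daily noncontact-injury prediction from GPS training load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily noncontact-injury prediction from GPS training load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurycast)
```

## The problem and the pipeline

Professional football clubs track external training load with GPS receivers:
hundreds of per-exercise metrics (player load, distances, velocity and
acceleration band counts, durations) for every player and session.
Noncontact injuries are rare — a fraction of a percent of player-days — and
multifactorial, so single-metric cutoffs identify them poorly. `injurycast`
implements a season-scale machine-learning pipeline that assigns every
player a daily injury probability:

1. **Aggregation** — exercise-level records are collapsed to one row per
   player per calendar day, each metric with an appropriate function (sums
   for loads, distances and counts; maxima for peak metrics; means for
   rates), plus descriptive variables (position, corridor, age in months,
   day of week, session type, match descriptors, exercise count, duration).
2. **Dummy days** — every player receives an all-zero row for every
   inactive calendar day, so the table has a continuous, shared time scale
   and the models can see rest/recovery hiatuses and sudden load changes.
3. **Adaptive winsorization** — per-metric clipping bounds are estimated
   from *injured players' records only* and applied to all records.
4. **Standardization** — per-column z-scores.
5. **mRMR ranking** — features ordered greedily by relevance to the injury
   label relative to redundancy with already-chosen features; a wrapper
   sweep then tests nested top-p subsets.
6. **Classifiers** — RBF-kernel SVM (Platt-scaled), a small feedforward
   network, and AdaBoost over decision stumps, each in cost-sensitive and
   traditional modes, trained on k-means-centroid-undersampled training
   splits.
7. **Validation and selection** — repeated player-disjoint two-fold
   validation; decision thresholds at the ROC elbow fitted on training
   splits; model selection by the geometric mean (GMEAN) of sensitivity and
   specificity.

## The synthetic season generator

Club GPS datasets are private, so the package ships a seeded generator
whose defaults emulate a single-club professional cohort: 34 players in
five positions (11/9/7/4/3 split), a 36-week September-to-May season with
six training days and roughly one match per week (occasional extra midweek
fixtures), 300 correlated nonnegative metrics, and 18 expected injuries —
about 0.2% of player-days. Metrics are correlated log-normal draws: a
common per-row intensity factor (weight `metric_corr`, default 0.5) plus
independent noise, exponentiated and scaled by session type. A match
exercise is scaled 4x a training drill, making the match the heaviest
single day of a normal week — a training day sums several short drills, a
match is one ~90-minute maximal effort — which reproduces the elevated
per-session injury risk of matches. A few metric columns are exact rescaled
duplicates (suffix `_alt`) so redundancy handling is genuinely exercised,
and two GPS-quality columns (HDOP, satellite count) are always present for
the preparation stage to drop.

**The injury hazard is a construct.** The underlying study is
observational and specifies no injury-generating mechanism, so the
generator's hazard is the package's own device, built to embody the
rationale for dummy days (sudden load changes and returns from rest carry
risk). An active day's probability is

$$p_d = \min\!\big(b \cdot e^{\beta_s \max(z_d, 0)} \cdot e^{\beta_r g_d},\, 1\big)$$

where $z_d$ standardizes the day's total load against the previous (up to)
seven days (rest days count as zero), $g_d$ flags an active day after two
or more idle days, and injuries can only occur on session days. Defaults
$\beta_s = 0.4$ and $\beta_r = 0.3$ are moderate effects chosen once; tests
that need unambiguous signal raise $\beta_s$ explicitly. When
`target_injuries` is set, `generate_season()` rescales the baseline $b$ by
a scalar root-solve so the summed daily probabilities equal the target —
this is what pins expected prevalence to the configured rate regardless of
the coefficients (the log-multiplier is capped at 700 to stay finite).
The pure per-day formula is exposed as `injury_probability()`.

What the generator does *not* emulate: biomechanical structure, 10 Hz
positional traces, heart rate or wellness data, injury severity and layoff
(injured players keep training), or seasonal periodization. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that it
recovers planted load-spike structure; they say nothing about predictive
performance on real cohorts.

## Preprocessing details

Winsorization bounds for metric $i$ use the median $\tilde{x}_i$, sample
standard deviation $\sigma_i$ (denominator $n-1$; the convention is the
package's choice), minimum and maximum of the *injured* records:

$$x_i^L = \tilde{x}_i - \big(\lfloor |{\min}_i| / \sigma_i \rfloor + 1\big)\sigma_i,
\qquad
x_i^U = \tilde{x}_i + \big(\lfloor |{\max}_i| / \sigma_i \rfloor + 1\big)\sigma_i$$

so each bound keeps at least one standard deviation of headroom and values
beyond a bound are replaced by it. Injury events legitimately live at
abnormal loads; fitting on injured records only prevents exactly those
values from being flattened. The absolute values inside the floor terms are
a deliberate deviation from the plain ratio: with a negative minimum (or
maximum) the unsigned ratio would place a bound on the wrong side of the
median. Raw GPS metrics are nonnegative, so the branch is essentially
never taken on realistic data. Metrics with $\sigma_i = 0$ (possible with
very few injured rows) are marked no-clip. With fewer than two injured
rows every metric is no-clip; with zero injured rows bounds are undefined
and fitting errors.

Standardization is the usual $(x - \bar{x}_i)/\sigma_i$ fitted on the full
winsorized table; constant columns pass through flagged. Dummy-day zero
rows are included when fitting (they are dataset rows; their inclusion is
stated here because the alternative is defensible too).

**Leakage.** The faithful protocol fits bounds, standardizer and feature
ranking on the complete dataset before splitting, reproducing the reference
workflow; this leaks test-set information into preprocessing. A
leakage-free variant (`run_config(..., leakage_free = TRUE)`) refits all
three inside each training fold for methodological comparison. It is off
by default deliberately: the default reproduces the protocol, the flag
quantifies its cost.

## Feature ranking

The classic mRMR criterion is defined for discrete variables via mutual
information; these features are continuous and no discretization is
prescribed, so the default variant is FCQ: relevance is the one-way ANOVA
F statistic of a feature against the binary label, redundancy the mean
absolute Pearson correlation with already-selected features, and the
greedy step maximizes their quotient (first feature: maximal relevance,
redundancy defined as 0, quotient guarded by
$\max(\text{redundancy}, 10^{-12})$). Ties break lexicographically by
feature name so rankings are deterministic. Both ingredients are invariant
to positive rescaling of a column, hence so is the ranking. A
mutual-information quotient variant with equal-width binning (default 10
bins) is available via `method = "miq"`. Zero-variance columns must be
removed first (`drop_zero_variance()`); an exact copy of a selected
feature is demoted by its unit correlation, which is what the duplicated
generator columns exercise.

## Classifiers and cost sensitivity

All three models consume standardized features and emit probabilities
strictly inside (0, 1):

* **SVM** — RBF kernel, squared-L2 regularization with `cost = 1` (the
  reference strength is unstated; 1 is the conventional default), via
  `e1071::svm`. Class weights scale the per-class penalty, adjusting the
  margin. Probabilities come from an in-package Platt calibration:
  stratified, seeded 5-fold cross-validated decision values, oriented
  toward the positive class, then a logistic sigmoid fitted with Platt's
  smoothed targets $\big((n_+ + 1)/(n_+ + 2),\ 1/(n_0 + 2)\big)$ so the map
  stays finite on separable data. The calibration is done in the package
  because libsvm's internal sigmoid proved unstable (it can invert) on the
  small undersampled training sets this pipeline produces.
* **FNN** — one hidden layer of 10 tanh units, inverted dropout at
  probability 0.6 before a sigmoid output, 20 epochs of Adam at learning
  rate 0.001, batch size 32, squared-L2 penalty ($10^{-4}$), class-weighted
  binary cross-entropy. A class-weighted squared-error loss is available
  via `loss = "squared"` (the reference description mentions both losses in
  different places; cross-entropy is the default as the more specific
  statement). Weight initialization is uniform fan-in; batch size and
  initialization are the package's choices where unstated. All randomness
  (init, shuffling, dropout masks) flows from one seed, so the loss
  trajectory is exactly reproducible.
* **AdaBoost** — discrete AdaBoost over one-level decision stumps, at most
  50. The weak learner is an exhaustive weighted search over every feature,
  every split between consecutive distinct values and both polarities, so
  fits are deterministic. Cost sensitivity enters through initial sample
  weights proportional to the class weights; the loop stops early when a
  stump achieves zero weighted error. Probabilities are the logistic
  transform of the doubled weighted vote.

Cost-sensitive class weights are $w_c = N/(2 n_c)$ — inversely
proportional to class frequencies — and are computed on the *original*
training split, not on the undersampled set fed to the optimizer. The
imbalance that motivates cost-sensitive learning is the dataset's (~0.2%
injury rate); after centroid undersampling the set the optimizer sees is
only mildly imbalanced (2.5:1), and weights computed there barely move any
model. Traditional mode sets both weights to 1.

**Undersampling.** Injured rows are kept verbatim; noninjured rows are
replaced by `round(n_injured / 0.40)` k-means centroids (injured:noninjured
= 0.40 after resampling). The reference description also reports k = 8,
which no single centroid-count rule can reconcile with the ratio and the
stated split sizes; the ratio semantics drives the count here, k is kept as
configuration metadata, and `use_k = TRUE` requests exactly k centroids
instead. If the requested count reaches the available (distinct)
noninjured rows the data pass through with a warning.

## Validation, thresholds, selection

Players injured at least once are shuffled (seeded) and split in half;
fold f trains on one half's rows and tests on the other half's rows plus
all never-injured players' rows. Folds are player-disjoint by
construction and the two training halves partition the injured players.
(The reference report's two fold totals differ by 99 rows for reasons it
does not explain; the folds here are complementary by construction.) Both
the fold assignment and model initialization are re-randomized every
repetition.

The decision threshold is the ROC elbow: candidate thresholds are the
distinct predicted scores plus a supremum point, a score counts as positive
at or above the threshold, and the elbow minimizes
$\sqrt{(1-\text{sens})^2 + \text{FPR}^2}$, ties resolving to the lower
threshold (favoring sensitivity: a missed injury costs more than a false
alarm). Thresholds are always fitted on the training split and reused on
the testing split. Metrics: sensitivity, specificity, accuracy, rank-based
AUC (ties averaged), and $\text{GMEAN} = \sqrt{\text{sens} \times
\text{spec}}$. Metrics whose denominator class is absent surface as `NA`
with an explicit flag, never as silent zeros.

The sweep enumerates model x learning mode x top-p; per repetition the two
folds are averaged, then mean and SD over repetitions summarize quality
and stability. Selection is three-step: per (model, mode) the p with the
highest mean training GMEAN (ties to smaller p, favoring parsimony), then
the group winners ranked by mean testing GMEAN. The reference protocol —
26 p-values, 500 repetitions, 78,000 runs — is expressible with
`sweep_grid()` defaults; routine runs use fewer repetitions. Every run's
seed is `derive_seed(base, coordinate, repetition)`, so any single run can
be re-derived in isolation.

## Problem sizes used by the test suite

The suite exercises the full-size default generator only where cheap;
statistical properties run on a scaled cohort chosen once: 20 players, a
12-week season block, 40 metrics, 12 expected injuries (the same ~0.3%
active-day hazard as the default). Signal-recovery checks use a
strong-spike scenario ($\beta_s = 1.5$, $\beta_r = 0.5$) so that planted
structure is unambiguous, and verify that the selected best model's mean
test AUC clearly exceeds both 0.70 and the same pipeline run on
label-permuted injuries (which sits near 0.5). The cost-sensitivity
direction — cost-sensitive training sensitivity at or above traditional
for SVM and FNN — is measured on training splits, which is where the
directional claim holds; on testing splits traditional learning can be the
more sensitive one.

## Known limitations

* The hazard model is a construct; none of its coefficients are estimates
  of real injury physiology.
* GMEAN-based selection with 18 injuries is high-variance; the reference
  protocol's 500 repetitions address stability, not bias.
* The faithful protocol's whole-dataset preprocessing inflates test
  metrics; use `leakage_free = TRUE` to quantify by how much.
* The FNN is intentionally minimal (one hidden layer, fixed width); it is
  not a general-purpose network implementation.
* Dummy rows zero *all* variables including age and day-of-week
  indicators — faithful to the all-zero rest-day signature, at the cost of
  physically meaningless zeros on those columns.
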