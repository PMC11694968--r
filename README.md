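# injurycast

Daily noncontact-injury risk prediction for professional footballers from
GPS-derived external training load.

Noncontact injuries are rare (a fraction of a percent of player-days) and
multifactorial; single-metric cutoffs and retrospective correlations
identify them poorly. `injurycast` implements a season-scale,
cost-sensitive machine-learning pipeline that assigns every player a daily
injury probability, for sports scientists and analysts working with
per-exercise GPS session exports: aggregation to a one-row-per-player-day
table with all-zero *dummy days* on rest days, adaptive winsorization with
bounds fitted on injured players' records only, per-column
standardization, greedy minimum-redundancy maximum-relevance (mRMR)
feature ranking with a nested top-*p* wrapper sweep, three classifiers
(RBF SVM with Platt scaling, a small tanh/dropout feedforward network,
AdaBoost over decision stumps) in cost-sensitive and traditional modes,
k-means centroid undersampling, player-disjoint two-fold validation with
ROC-elbow thresholds, and GMEAN-based model selection. Club GPS data are
private, so a seeded synthetic season generator with a load-spike injury
hazard stands in for the cohort and makes every stage testable.

## The method in brief

Winsorization bounds for metric $i$ come from injured records only
(median $\tilde{x}_i$, sample SD $\sigma_i$, extrema $\min_i$, $\max_i$):

$$x_i^L = \tilde{x}_i - (\lfloor |\min_i|/\sigma_i \rfloor + 1)\,\sigma_i,\qquad
  x_i^U = \tilde{x}_i + (\lfloor |\max_i|/\sigma_i \rfloor + 1)\,\sigma_i,$$

values beyond a bound are replaced by it, then columns are standardized to
$z$-scores. Features are ranked greedily: first the feature with maximal
relevance (ANOVA F against the binary injury label), then repeatedly the
feature maximizing relevance over mean absolute correlation with the
already-selected set. Cost-sensitive class weights are
$w_c = N/(2 n_c)$. Decision thresholds sit at the ROC elbow — the point
minimizing $\sqrt{(1-\mathrm{sens})^2 + \mathrm{FPR}^2}$, fitted on
training splits only — and models are compared by
$\mathrm{GMEAN} = \sqrt{\mathrm{sensitivity} \times \mathrm{specificity}}$,
averaged over repeated player-disjoint two-fold splits. See the methods
vignette (`vignettes/injury-prediction-methods.Rmd`) for the full account.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, each a
thin script over the package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1   # synthetic season -> CSVs
Rscript analysis/02_prepare.R             # player-day table
Rscript analysis/03_preprocess_rank.R     # winsorize, standardize, mRMR
Rscript analysis/04_sweep.R --seed 1      # model x mode x top-p sweep
Rscript analysis/05_select.R              # three-step best-model selection
```

With seed 1 this prints, step by step:

```
Simulated 21459 exercise records for 34 players over 255 days.
Injuries: 18 (7 in matches, 38.89%; 11 in training).
Player-day table: 8670 rows (34 players x 255 days), 327 feature columns.
Dummy (rest) rows: 1509 (17.4%); injury rows: 18 (0.208% of player-days).
Winsorized 327 metrics (1 no-clip); dropped 0 zero-variance columns.
Ranked 327 features by mRMR; top 5: metric_017, max_velocity_ms, ...
Sweeping 120 runs (24 coordinates x 5 repetitions)...
Overall best: fnn (cost_sensitive) with 80 features, test GMEAN 62.81%.
```

Reading: the generator drew a 36-week season for 34 players with 18
injuries — about 0.2% of player-days, the class imbalance that motivates
the cost-sensitive machinery. Every player-day became one row (rest days
as all-zero dummy rows). The sweep trained every classifier and learning
mode on nested mRMR feature subsets with repeated player-disjoint folds;
selection first picks each group's feature count by training GMEAN, then
ranks groups by testing GMEAN. Here the cost-sensitive network won with a
balanced test performance of 62.81% GMEAN; per-group winners and their
full metric blocks land in `results/best_model_metrics.csv`. This driver
sweeps a reduced grid (4 feature counts, 5 repetitions) — the reference
protocol (26 feature counts, 500 repetitions, 78,000 runs) uses the same
code path via `sweep_grid()` defaults.

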