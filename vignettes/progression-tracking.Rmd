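---
title: "Semi-supervised tracking of ALS functional decline: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised tracking of ALS functional decline: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(alstrack)
```

## The problem

ALS functional decline is tracked with the revised ALS Functional Rating
Scale (ALSFRS-R): twelve items, each scored 0 (dependent) to 4 (normal),
summed into a 0–48 composite. Assessments are collected monthly by telephone
and quarterly at clinic visits, so weeks can pass between observations while
continuous in-home sensors (bed-mounted ballistocardiogram channels for
respiration, pulse and restlessness; passive-infrared room motion counts)
record daily behaviour. `alstrack` implements a semi-supervised pipeline
that expands the sparse assessments into daily *pseudo-labels*, summarizes
the sensor streams into daily day/night features, and fits boosted-tree
regressions of the pseudo-labels on the features under three learning
paradigms, so that between-visit functional status can be estimated at
sensor frequency.

Because the motivating study's data are restricted, the package ships a
seeded synthetic-cohort generator that reproduces the statistical shape of
such a case series and provides ground-truth latent trajectories, making
every downstream stage testable.

## The synthetic cohort generator

`cohort_config()` defaults encode the study conditions: three participants,
enrollment lengths 599/236/219 days, assessments every 30 days starting at
enrollment day 0 with every third flagged as a clinic visit, and a 5%
missing-day dropout (the observed gap between enrollment length and usable
train+test days implies missing days). Each subscale follows one of three
progression profiles:

* **homogeneous** — all participants share a per-scale template decline
  rate; they differ only by a starting-level offset (one offset mechanism,
  uniform on ±0.4);
* **heterogeneous** — participant-specific rates spread over a 4-fold range
  around the template;
* **plateau-drop** — periods of stability punctuated by sudden unit drops.

Template rates are drawn uniformly on 0.004–0.020 units/day. This range was
calibrated once so that integer assessment scores over study-length
enrollments produce per-subscale variances spanning roughly 0–2.4, the
magnitude observed in comparable case-series data; slower rates produce
almost-flat integer scores and an untestably degenerate cohort. Trajectories
are monotone nonincreasing up to a small uniform jitter (±0.05) and clipped
to the scale domain, so fast progressors floor at 0 — exactly the
zero-variance cells that real studies report as unmodelable dashes.

Sensor channels couple linearly to the composite latent: the daily mean of
channel $c$ is $\beta_c + \lambda_c L_t + \varepsilon$, with
$\varepsilon \sim N(0, \sigma_c)$. Default loadings are physiologically
signed and sized (respiration rate and pulse rise, motion falls as function
declines; e.g. pulse −0.40 bpm and living-room motion +0.35 counts/h per
composite point, noise SD 1). A mean-preserving day/night amplitude split
makes segmentation informative, and intra-day samples default to 1/min for
bed channels and hourly counts for motion. With zero noise the daily mean
equals the coupling formula exactly, and with known noise an OLS regression
of daily means on the latent recovers the loading — both are tested
properties.

Fixture presets (`make_fixture()`) use enrollment lengths 211/181/241 so the
final monthly assessment falls on the last enrolled day, emulating a closing
assessment at study exit. Without this, the last 15–29 days of record lie
beyond the final anchor where pseudo-labels are constant by construction,
and the 20% test window would be mostly flat.

## Pseudo-labeling

Three interpolators expand anchors (assessment day, observed score) to a
daily series:

* `interpolate_linear()` — piecewise linear between anchors, constant
  extension outside them; the clinical-slope baseline.
* `interpolate_cubic()` — a natural cubic spline through the anchors
  (second derivatives zero at the ends), clipped to the scale domain,
  constant outside the anchor range. With exactly two anchors it equals the
  linear interpolant. Tests verify it against an independent tridiagonal
  second-derivative solve.
* `interpolate_attention()` — a shallow transformer encoder per sensor
  channel, ensembled by pointwise averaging.

The attention interpolator maps date-indexed feature vectors (one channel's
day/night statistics plus a normalized day-index positional input) through a
linear embedding, one block of 2-head scaled dot-product self-attention with
residual connections and a ReLU feed-forward net, and a linear read-out
(defaults: width 32, feed-forward 64, 200 full-batch Adam epochs at learning
rate 1e-3, no early stopping — full-batch fixed-epoch training keeps the
output a deterministic function of the seed). It is trained by mean squared
error on anchor days only and evaluated on all days, yielding a smooth
sensor-informed daily curve rather than crisp labels. Two implementation
choices matter:

* targets are standardized by the anchor mean and SD, and the read-out layer
  is zero-initialized, so the untrained model predicts the anchor mean and
  training fits residuals — this makes constant targets exact and stabilizes
  convergence at the default learning rate;
* the regression target is the score itself (`target_mode = "score"`); a
  `delta` mode that predicts per-day change and integrates it forward from
  the most recent anchor is provided, but score-scale curves are the
  default because that is what the interpolation is meant to produce.
  Observed scores are never fed as inputs at inference, so the model cannot
  trivially copy them.

All gradients are analytic (hand-derived backpropagation through softmax
attention) and are verified against central finite differences in the test
suite.

## Feature engineering

Samples are tagged day/night by a half-open clock window, default
06:00–22:00 (the field reports no standard hours). Per channel × period ×
date, 17 summary statistics are computed: count, min, max, mean, median,
mode, variance, range, skew, kurtosis, q10/q25/q75/q90, IQR, CV and entropy.
Conventions the implementation fixes where the field leaves them open:
standardized-moment skew and excess kurtosis; linear-interpolation (type 7)
quantiles, with q10/q25/q75/q90 as the quantile set; Shannon entropy
(natural log) over a fixed 10-bin histogram of the cell's range; the mode of
values rounded to 2 decimals with ties to the smallest; CV guarded to 0 when
|mean| < 1e-12. Every statistic is cross-checked against a naive
reimplementation to 1e-9.

Collinear features are removed by a greedy keep-first scan in fixed column
order (|Pearson r| > 0.95 with an earlier retained column, zero-variance
columns dropped as "constant"), and the result is min–max scaled. Both
decisions are fit on training rows only; the stored transform is applied
unchanged to test rows, which may therefore leave [0, 1]. Pearson
correlation is invariant under min–max scaling, so the order of the two
steps is immaterial.

One protocol detail is load-bearing for transfer learning: the
normalization ranges for *every* participant are fit on their earliest 80%
(`train_fraction`) of rows. With a uniform protocol, "feature = 1" means
the same relative disease stage for every participant, and the leave-in
participants' remaining rows supply out-of-range (>1) late-stage training
signal — precisely the region where the holdout's unseen test window lives.
Fitting leave-in ranges on their full record instead silently misaligns the
feature scale across participants and biases every transferred model. A
`paper_faithful` switch fits ranges on all rows, reproducing the
order-ambiguous historical variant.

## Learning paradigms

Each holdout participant's supervised table is split sequentially: the
earliest `floor(0.8 N)` observations train, the rest are the unseen test
set (389/98, 128/33 and 156/40 days at the case-series sizes). Targets with
training variance below 0.01 are not modeled individually; zero-variance
(static) targets are excluded from transfer fine-tuning as well.

* **Individual batch** — boosted regression on the holdout's training rows.
* **Cohort transfer + batch fine-tuning** — a base model fit on the shuffled
  pooled rows of the leave-in participants (leave-one-participant-out), then
  resumed for 32 additional boosting rounds on the holdout's full training
  partition. The base artifact stores the sorted training-row ids and their
  hash; `verify_lopo()` proves the holdout's absence.
* **Cohort transfer + incremental fine-tuning** — a prequential walk over
  the holdout's training rows in date order: predict the incoming
  observation with the current state, then resume boosting for k = 1 round
  on the window of the most recent 14 rows. The window default approximates
  two weeks of between-visit adaptation; predictions at step *t* are provably
  invariant to any change in later rows.

Hyperparameters are tuned by randomized search over the nine-dimensional
candidate grid (learning rate, trees, gamma, depth, min child weight, row
and column subsampling, L2, L1), scored by 3-fold cross-validated RMSE —
chronological blocks within a participant, shuffled folds for the pooled
cohort. The tuned model's split-frequency importances then drive a
precision-rounding screener: at p = 6, 7, 8, … decimals the candidate subset
holds features whose importance rounded at p is positive (so finer precision
admits smaller importances and subsets grow), capped at the 200 most
important; each subset is refit and the configuration with the lowest
selection RMSE wins, ties to the smaller subset. Selection is scored on an
internal validation slice — the last 20% of training rows — rather than the
test set; selecting on test RMSE, which the historical procedure describes,
leaks the evaluation data into model choice, and is available only behind
`paper_faithful = TRUE` for auditability. Fine-tuned models inherit the base
model's hyperparameters unchanged.

Checkpoints serialize the booster binary next to a JSON sidecar (version,
feature list, hyperparameters, provenance including the parent checkpoint
hash, and an md5 content hash verified on load). A continuation of zero
rounds returns the base model object itself: the underlying library treats
`nrounds = 0` continuation as non-trivial, so the identity is enforced
explicitly.

## Evaluation

Per evaluated cell (participant × scale × interpolation × paradigm) on the
test window: RMSE with a nonparametric bootstrap interval — 1,000 resamples
of the paired values, each recomputing the *centered* error
$E' = \sqrt{\sigma_y^2 + \sigma_{\hat y}^2 - 2\sigma_y\sigma_{\hat y}|r|}$
from the two standard deviations and the absolute correlation, with
percentile 2.5/97.5 bounds — and Pearson r with a Fisher-z interval
($z = \mathrm{atanh}\,r$, $se = 1/\sqrt{n-3}$), marked missing below four
points. Degenerate correlations (either side constant) are reported as 0
with a flag, matching the "0 (0–0)" table convention. A residual-bootstrap
alternative recomputing plain RMSE per resample is available for comparison
with the centered form, which deliberately omits the mean-bias term.

Standard deviations here are population (1/n) SDs, the Taylor-diagram
convention; under it the identity
$E'^2 = \sigma_{ref}^2 + \sigma_{pred}^2 - 2\sigma_{ref}\sigma_{pred}r$
holds to machine precision and $\mathrm{RMSE}^2 = E'^2 + \mathrm{bias}^2$
decomposes exactly. `taylor_point()` emits the polar coordinates
($\sigma_{pred} r$, $\sigma_{pred}\sqrt{1-r^2}$) with the reference at
($\sigma_{ref}$, 0) and a zero-variance prediction at the origin.

Cross-participant numbers are formed only by `aggregate_mean_tci()` — mean
with a t-distribution interval on the standard error of the mean, never an
interval at n = 1. Contrast tables mark the best cell per row and flag a
cell significantly better than another when their 95% intervals are
disjoint in the favorable direction; the historical tables print "(p<0.05)"
without naming a test, so CI-disjointness is this package's explicit
definition, not an inherited one.

## Problem sizes, determinism and reproducibility

One master seed derives every stage seed through `derive_seed()`, a labeled
polynomial hash; identical config + seed yields byte-identical CSV outputs,
including under subsampled boosting (single-threaded training with an
explicit seed). The test suite and the acceptance script run reduced problem
sizes chosen as the package's own desk-scale conditions: 3 participants of
211/181/241 days at 96 bed samples/day, two subscales plus the composite,
all three interpolations and paradigms, 2 random search draws, 200 bootstrap
resamples, 40 attention epochs; the structure-recovery study uses 10 seeded
replicates with fixed mid-grid hyperparameters (eta 0.1, 128 trees, depth
3) so that the comparison isolates the paradigms rather than the tuner.

## What the synthetic experiments do and do not show

The generator produces linear-in-latent sensor couplings, Gaussian daily
noise, uniform assessment cadence and missingness that is independent of
disease state. Real in-home data have none of these simplicities:
nonstationary behaviour, device outages correlated with health events,
caregiver presence, and sensor drift. Passing tests therefore demonstrate
that the pipeline's machinery is correct and that it *can* recover planted
cohort structure — not that the paradigm orderings observed on any real
cohort will reproduce.

Two recovery properties are asserted over 10 seeded replicates. On
homogeneous cohorts, transfer with batch fine-tuning matches or beats
individual batch test RMSE in 8 of 10 seeds: individual models cannot
extrapolate below their training label range, while the cohort base has seen
the late-stage regime of the leave-in participants. On heterogeneous
cohorts, the asserted ordering — incremental fine-tuning achieving higher
test correlation than batch fine-tuning — does **not** emerge under this
generator (2–5 of 10 seeds across the designs examined). The mechanism is
instructive: with evaluation by the final post-adaptation model state,
test-window correlation is driven entirely by the model's feature response,
and the many small recency-weighted incremental updates dilute the cohort
feature response toward locally constant corrections, whereas 32 rounds of
batch fine-tuning preserve it. The correlation advantage that incremental
adaptation shows on the real case series presumably rests on properties of
the real sensor–label coupling (e.g. regime shifts between visits) that a
linear stationary coupling cannot produce. The corresponding acceptance
check is left failing rather than weakened, and this section is its
analysis.

Other known limitations: pseudo-labels beyond the final assessment are
constant by construction, so trailing unassessed days carry no decline
signal; the attention interpolator's daily estimates are used as regression
targets without uncertainty; and the composite is modeled directly from
composite pseudo-labels, not as a sum of subscale predictions.
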