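---
title: "Methods: individualized next-day behavior prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized next-day behavior prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modeling stance

Some residents of long-term care facilities with autism spectrum disorder
exhibit challenging behaviors — aggression (AGG) and self-injurious
behavior (SIB) — whose likelihood appears linked to co-occurring
conditions (sleep disruption, gastrointestinal problems) and to the
environment.  Knowing a day in advance that a behavior is likely lets
caregivers plan supervision and scheduling.  behaviorcast implements a
per-individual analysis of this question: each person gets their own
binary classifier that predicts, from variables observed about day *d*,
whether a target behavior occurs on day *d + 1*.  A population-level model
is deliberately out of scope: behavior/factor relationships are too
heterogeneous across individuals for a pooled model to be useful, so
heterogeneity is handled by fitting one model per person and summarizing
across people afterwards.

## Data model and cleaning rules

Six daily sources per individual are aligned on a calendar axis
(`build_daily_records()`):

* **Behavior** is logged per 8-hour shift (07–15, 15–23, 23–07).  A day is
  a *behavior day* if at least one recorded shift shows a target-category
  behavior, a *no-behavior day* if all recorded shifts show none, and
  *excluded* if any shift is missing (leave of absence, unrecorded) or was
  collected by time sampling, which is incompatible with event counting.
  When a day is both time-sampled and missing, the time-sampling reason is
  reported; either way the day is excluded.
* **Sleep** (nightly bed checks) gives hours and interruptions; hours are
  clamped to [0, 24] rather than dropped, because out-of-range entries are
  data-entry slips around real nights.  The night is attributed to the
  evening date: the sleep predictor for day *d* is the night running into
  the morning of *d + 1*, matching the 07:00 start of the behavior day.
* **Bowel movements** arrive as events.  Parent-reported events are
  dropped (the resident was away); a valid event needs a Bristol score, a
  size, or a staff note.  Days aggregate to count, mean/min/max Bristol;
  no-BM days are coded Bristol 0.  A valid event without a Bristol score
  counts toward the day's total but not the Bristol aggregates — the only
  composition honoring both the note-only validity rule and the numeric
  aggregation.  Because BMs were sometimes logged only when they happened,
  a run of more than 3 observed no-BM days without an explicit no-BM
  indication turns subsequent days missing until the next recorded BM
  (`apply_bm_buffer()`).  The reader therefore requires an explicit
  `no_bm` marker column to distinguish confirmed absence from silence.
* **Allergen** station counts are sparse: zeros are imputed before the
  first and after the last observation of each calendar year, and gaps in
  between carry the last observation forward.
* **Weather** values carry per-value station quality flags; a raised flag
  discards that value only, not the whole day, since flags attach to
  individual elements.
* **Lunar** records (sampled 07:00) substitute 00:00:00 / 23:59:59 for a
  moon rise / set that did not occur, convert times to fractions of an
  86 400 s day, zero absent shadows, reduce phase to illumination percent,
  express moon age as a percent of the 29.530588-day cycle, and truncate
  next-new/full-moon intervals to whole days.

Cleaning never fabricates an observation outside these cited fill rules,
and each cleaner is idempotent on its own output.

## Features, cohorts, and standardization

Fifteen predictors are retained (one representative per environmental
category): `bm_count`, `bristol_mean/min/max`, `bm_intervention`,
`constipation`, `diarrhea`, `abnormal_bm`, `extreme_bristol_diff`,
`menses`, `sleep_hours`, `sleep_interruptions`, `allergen_total`,
`tmax_f`, `moon_illum_pct`.  Engineered GI flags: constipation = min
Bristol < 3, no BM, or an intervention; diarrhea = more than 3 BMs or max
Bristol > 5; abnormal = either side, >3 BMs, no BMs, or an intervention;
`extreme_bristol_diff` is the larger distance of the day's min/max Bristol
from the optimal 3.5.  The min/max convention (rather than the mean) was
chosen so that any single abnormal event flags the day.  Days with BMs but
no Bristol information evaluate only the count/intervention clauses and
are dropped from modeling through their missing `extreme_bristol_diff`;
no imputation is attempted.

All variables, binary flags included, are z-scored with the
population (divide-by-*n*) moments pooled over all included individuals.
Pooling across the whole population (not per cohort) was chosen where the
alternative was defensible; it only rescales weights, and the choice is
exposed through `standardize_rows()`.  Menses is constant zero for male
individuals but is retained in the pooled standardization (variance comes
from the females); the reporting layer restricts menses importance
counts to females.

Inclusion per target cohort: residency, age < 19 at the individual's data
start (admission + 1 calendar month, or the latest first record of
behavior/sleep/GI), a confirmed ASD diagnosis, at least 20 model-ready
rows, and majority-class fraction at most 0.90 (strictly above excludes —
"maximum threshold of 90%" read as an allowed maximum).  The 20-point
minimum is applied to model-ready rows, i.e. after dropping rows with
missing predictors, since those are the rows the split protocol sees.
Each target (AGG, SIB, BOTH) recodes the same shift records, so an
individual with 80% aggression days and 20% self-injury days joins AGG
and SIB but not BOTH.

## The classifier

Inputs are mapped by a direct kernel transformation against *m* = 15
prototypes \(p_j\) drawn uniformly without replacement:

\[ f_{ij} = \exp\left(-\lVert x_i - p_j \rVert^2 / \sigma\right) \]

and a single-layer ADALINE (weights \(w\), bias \(b\)) is trained on the
features by the sequential Widrow–Hoff rule for 1000 epochs, with the
logistic activation producing \(\hat p = \mathrm{logit}^{-1}(w^\top f + b)\).

Choices the source description leaves open, fixed here and configurable:

* **Prototype sampling.**  Prototypes are drawn from the *training
  portion* of each split rather than the entire set, to avoid validation
  leakage; the literal any-row reading is available by fitting on the full
  data.
* **Kernel parameter.**  \(\sigma\) defaults to the median of pairwise
  squared Euclidean distances among the training rows (median heuristic);
  a constant override is accepted.
* **Update rule.**  The per-sample update uses the error on the
  *logistic-activated* output, \(w \leftarrow w + \eta\,(y - \hat p)\,f\)
  (the delta rule for a logistic unit).  The textbook pre-activation LMS
  update with {0,1} targets is retained as `update_rule = "linear"`, but
  it is degenerate in this protocol: its regression output concentrates in
  [0, 1] around the base rate, so `plogis(output)` exceeds 0.5 almost
  everywhere and the 0.5-threshold classifier collapses to one class.
  Since the network output is specified to be a probability, the logistic
  error is the consistent reading.
* **Learning rate** \(\eta = 0.01\) with per-epoch reshuffling under the
  split seed; **threshold** 0.5 on the probability.
* **Split seeds** are the integers 1–30.  The original analysis generated
  its splits with Threefry-keyed streams in MATLAB; seeds here map to R's
  default generator, so split membership is not bit-for-bit comparable,
  only distributionally.

Evaluation: 30 random 85:15 splits per individual; each split reports
sensitivity, specificity, and the balanced classification rate
BCR = (sensitivity + specificity)/2, the metric of record under class
imbalance.  Splits whose validation (or training) portion contains a
single class are marked invalid and excluded from aggregates.  A
ridge-stabilized logistic regression (`glmnet`, \(\alpha = 0\),
\(\lambda = 10^{-6}\) — large enough only to guarantee existence under
separation) on the original standardized variables is evaluated under the
identical protocol as the linear benchmark.

## Variable importance and downstream summaries

Importance of variable *k* is the standard deviation of the network's
probability output over 1000 inputs whose *k*-th component is standard
normal and all others 0 (the standardized mean).  The probability output
was chosen over the pre-activation: "network output" is ambiguous, both
orderings are monotone-related, and the probability is the quantity the
model reports; the excitation seed stream is independent of training
seeds.  Raw spreads are scaled proportionally so the maximum is exactly 8
(raw spreads are already bounded below by 0, so a min–max shift would
distort true zeros); scaled values above 2 are significant, below 0.5
negligible, between them minor, with a stricter plotting cutoff at 4.
Population summaries count individuals above the cutoffs per variable,
menses over females only.

Variables of the individuals whose mean BCR exceeds 0.80 (mean over valid
splits; the qualification statistic is configurable) are clustered
agglomeratively with average linkage on the distance
\(1 - |\mathrm{Pearson}\ r|\) over their pooled standardized rows — the
absolute value because sign is irrelevant to redundancy — and the
dendrogram is cut at three clusters and serialized to Newick.  Clustering
operates on the standardized data, not model-derived quantities.

## The synthetic world

`generate_cohort()` states the world the tests run in.  Raw sources are
drawn first (sleep ~ N(8, 1.2) hours with ~1% out-of-range corruptions,
Poisson(1.1) BM events with individual-shifted Bristol scores and a 4%
parent-report rate, 8% daily intervention rate, an Apr 1–Sep 30 allergen
season observed on 70% of days, sinusoidal-seasonal weather with 2%
quality-flag rates, and lunar variables on the true 29.530588-day cycle
with ~3% non-occurring rises/sets).  The day-(d+1) behavior probability is
then computed from the day-*d* *engineered, z-scored* features — the same
transformation the model sees — so generating weights and recovered
importance live on one scale.  Mechanisms:

* `logistic_additive`: \(p = \mathrm{logit}^{-1}(b_0 + w^\top z)\), with
  \(b_0\) calibrated by root-finding so the mean probability equals the
  configured base rate (default 0.3, a typical minority-behavior
  individual).
* `null`: constant base rate, independent of all predictors.
* `xor_nonadditive`: probability 0.95 when exactly one of two designated
  indicators is active, 0.05 otherwise.  The indicators are the
  above-median signs of `sleep_hours` and `tmax_f` rather than the
  engineered binary flags: the flags' realistic prevalences sit far from
  0.5 and are logically nested (an intervention implies the constipation
  flag), which would make an XOR on them partially visible to a linear
  model; sign indicators of continuous variables are balanced by
  construction, giving a pure non-additive rule.  The near-deterministic
  0.95/0.05 levels are chosen because this mechanism exists to probe
  nonlinear capacity, not noise tolerance.

Individuals are generated independently (nothing is known about
inter-individual correlation of behavior rates).  Leaves of absence blank
the resident-collected sources only — behavior shifts become `missing`,
sleep/BM rows disappear — while station data (allergen, weather, moon)
persist, as a resident's absence cannot erase station records; the
affected days are excluded downstream by the shift-missing rule either
way.  Time-sampled shifts are re-marked, not deleted, and gap dates remain
recoverable on the cohort object.

What a green test on this world establishes: that the pipeline's rules,
alignment, protocol, and recovery behave as specified under known truth.
What it does not establish: performance on clinical data — real sources
have autocorrelated missingness, changing collection protocols, and
medication/illness covariates the generator does not emulate (and which
the analysis excludes by design).

## Numerical and degenerate-input choices

* Standardization drops zero-variance variables (population SD
  ≤ 1e−12) and reports them; fewer than two pooled rows abort.
* `median_sigma()` falls back to 1 when fewer than two distinct rows
  exist or the median distance is 0.
* Negative round-off in squared distances is clamped at 0 before the
  exponential.
* Training with fewer rows than prototypes downgrades the prototype count
  with a warning; a single-class training set aborts.
* All-zero excitation spreads yield an all-negligible profile with a
  warning rather than dividing by zero.
* Correlation of a zero-variance column is treated as 0 (maximal
  distance) in clustering.
* Every stochastic step (generation, splits, prototype draws, epoch
  shuffles, excitation draws) is seeded; sub-seeds are derived
  arithmetically below \(2^{31}\).

## Known limitations

The kernel ADALINE's capacity is modest by construction: 15 radial-basis
features cannot represent interactions confined to a few of 15
standardized dimensions when the remaining dimensions dominate pairwise
distances (the suite's non-additive stress case documents this
honestly — its training BCR plateaus near 0.6 while the mechanism's
information ceiling is 0.95).  Likewise, with moderate generating weights
the information ceiling of the additive world (the Bayes classifier's own
BCR) is in the high 0.7s, and no evaluation protocol can exceed it.  The
analysis predicts one day ahead from one prior day only; longer lags,
imputation, and population-level pooling are out of scope.
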