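# behaviorcast

Individualized next-day prediction of challenging behavior — aggression
(AGG) and self-injurious behavior (SIB) — for residents of a long-term
care facility with autism spectrum disorder, from daily records of
co-occurring conditions and the environment.  The package is aimed at
biostatisticians and clinical data scientists working with routinely
collected residential care data: it turns six messy daily sources
(behavior logs per 8-hour shift, nightly sleep checks, bowel-movement
events with Bristol scores, menses, pollen counts, weather station
values, lunar ephemerides) into one model-ready matrix per person, and
fits one classifier per person, because behavior/factor relationships
are too heterogeneous for a pooled model.

## The model

Day-*d* predictors (15 variables: GI count/Bristol aggregates and
engineered constipation/diarrhea/abnormal flags, menses, sleep hours and
interruptions, total allergen, maximum temperature, lunar illumination),
z-scored over the pooled population, are mapped by a direct kernel
transformation against *m* = 15 prototype vectors *p<sub>j</sub>*
sampled from the training data:

> *f<sub>ij</sub>* = exp( −‖ *x<sub>i</sub>* − *p<sub>j</sub>* ‖² / σ )

A single-layer ADALINE (weights *w*, bias *b*) on these features is
trained by the sequential Widrow–Hoff rule for 1000 epochs, and the
logistic activation yields the probability that the target behavior
occurs on day *d + 1*.  Each individual's model is evaluated over 30
random 85:15 train/validation splits by the balanced classification rate
BCR = (sensitivity + specificity)/2 — the metric of record under class
imbalance — with one-class validation splits excluded.  A
ridge-stabilized logistic regression on the untransformed variables is
the linear benchmark under the identical protocol.  Variable importance
is measured by excitation: drive one standardized variable with 1000
standard-normal draws, hold the rest at 0, record the spread of the
output, and scale spreads so the largest is 8 (significant > 2,
negligible < 0.5, plotted > 4).  Predictor redundancy is summarized by
average-linkage clustering on 1 − |*r*| for individuals whose BCR
exceeds the clinical 80% threshold.

A synthetic-cohort generator with known ground truth (additive-logistic,
non-additive XOR, and null mechanisms; leaves of absence; time-sampled
shifts; seasonal allergens; lunar cycles) makes every stage testable
without clinical data.  See the methods vignette
(`vignettes/behaviorcast-methods.Rmd`) for the full account.

## Worked example

```r
library(behaviorcast)

cfg <- synth_config(n_individuals = 1, days_per_individual = 400,
                    behavior_mechanism = "logistic_additive",
                    effect_weights = c(constipation = 2, sleep_hours = -1.5),
                    base_rate = 0.3, seed = 42)
cohort <- generate_cohort(cfg)
ind    <- cohort$individuals$ind001

daily  <- engineer_gi(build_daily_records(ind))     # clean + GI features
labels <- code_behavior_days(ind$behavior, "BOTH")  # day coding
rows   <- align_days(daily, labels)                 # day d -> label d+1
std    <- standardize_rows(rows)                    # pooled z-scores
x <- as.matrix(std$rows[, std$params$variable])

evaluate_splits(x, std$rows$y, n_splits = 30)
#> kernel model: 30/30 valid splits
#>   mean BCR 0.749 (median 0.747); sens 0.641, spec 0.857; majority 0.68

evaluate_splits(x, std$rows$y, n_splits = 30, method = "linear")
#> linear model: 30/30 valid splits
#>   mean BCR 0.802 (median 0.809); sens 0.715, spec 0.889; majority 0.68

fit <- fit_kernel_adaline(x, std$rows$y, seed = 1)
imp <- variable_importance(fit, seed = 1)
head(imp[order(-imp$scaled), c("variable", "scaled", "tier")], 5)
#>                        variable   scaled        tier
#> sleep_hours         sleep_hours 8.000000 significant
#> bm_intervention bm_intervention 2.940234 significant
#> abnormal_bm         abnormal_bm 2.862934 significant
#> constipation       constipation 2.817434 significant
#> bristol_min         bristol_min 2.309606 significant
```

The mean BCR of ~0.75 says the kernel model recovers most of the planted
signal (this additive world's own Bayes classifier scores ~0.80 under the
same protocol: the generating log-odds spread is ‖w‖ = 2.5, so much of
the day-to-day outcome is irreducible noise).  The importance profile
correctly surfaces the two planted drivers — sleep hours and the
constipation-related GI block, whose variables share credit because they
are generated from the same bowel-movement draws.

`run_pipeline(pipeline_config(...), out_dir)` chains all stages —
generation (or `read_cohort()` on prepared CSVs), cleaning, feature
alignment, the inclusion cascade, both classifiers, importance, and the
report tables — writing per-stage CSVs, a run log of every dropped
day/row/individual, and an MD5 manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main analysis from scratch: it generates a
5-individual synthetic cohort under the given seed, runs the full
pipeline (all three cohorts, 30 splits, kernel + linear models,
importance, reports) against the installed package, prints per-cohort
summaries, and writes the results JSON to `--out`.
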