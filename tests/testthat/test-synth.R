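test_that("config validation rejects bad probabilities and unknown weights", {
  expect_error(synth_config(base_rate = 1.2), "probabilities")
  expect_error(synth_config(loa_gap_rate = -0.1), "probabilities")
  expect_error(synth_config(effect_weights = c(nonexistent_var = 1)),
               "unknown variable")
  expect_silent(synth_config(effect_weights = c(constipation = 2)))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_individuals = 2, days_per_individual = 90,
                      loa_gap_rate = 0.02, time_sampling_rate = 0.01, seed = 77)
  c1 <- inject_missingness(generate_cohort(cfg), cfg)
  c2 <- inject_missingness(generate_cohort(cfg), cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  ## and the written CSVs are byte-identical too
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  f1 <- write_cohort(c1, d1); f2 <- write_cohort(c2, d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  ## a different seed changes the draw
  cfg3 <- synth_config(n_individuals = 2, days_per_individual = 90, seed = 78)
  expect_false(identical(generate_cohort(cfg3)$truth, c1$truth))
})

test_that("null mechanism realizes its base rate within binomial error", {
  cfg <- synth_config(n_individuals = 1, days_per_individual = 400,
                      behavior_mechanism = "null", base_rate = 0.5, seed = 1)
  co <- generate_cohort(cfg)
  ## 95% binomial interval for n = 400: 0.5 +/- 0.049
  expect_lt(abs(co$truth[[1]]$realized_rate - 0.5), 0.06)
})

test_that("a positive constipation weight raises next-day behavior probability", {
  cfg <- synth_config(n_individuals = 1, days_per_individual = 1000,
                      behavior_mechanism = "logistic_additive",
                      effect_weights = c(constipation = 2), base_rate = 0.3,
                      seed = 2)
  ind <- generate_cohort(cfg)$individuals[[1]]
  daily <- engineer_gi(build_daily_records(ind))
  lab <- code_behavior_days(ind$behavior, "BOTH")
  y_next <- as.integer(lab$label[match(daily$date + 1, lab$date)] == "behavior")
  ok <- !is.na(daily$constipation) & !is.na(y_next)
  p1 <- mean(y_next[ok & daily$constipation == 1])
  p0 <- mean(y_next[ok & daily$constipation == 0])
  expect_gt(p1, p0)
})

test_that("marginal association signs recover the configured weights", {
  for (w in list(c(constipation = 2), c(sleep_hours = -1.5))) {
    cfg <- synth_config(n_individuals = 1, days_per_individual = 400,
                        behavior_mechanism = "logistic_additive",
                        effect_weights = w, base_rate = 0.35, seed = 4)
    ind <- generate_cohort(cfg)$individuals[[1]]
    daily <- engineer_gi(build_daily_records(ind))
    lab <- code_behavior_days(ind$behavior, "BOTH")
    rows <- align_days(daily, lab)
    est <- cor(rows[[names(w)]], rows$y)
    expect_equal(sign(est), sign(unname(w)))
  }
})

test_that("null-mechanism labels are independent of generated predictors", {
  pvals <- vapply(1:8, function(s) {
    cfg <- synth_config(n_individuals = 1, days_per_individual = 250,
                        behavior_mechanism = "null", base_rate = 0.4, seed = s)
    ind <- generate_cohort(cfg)$individuals[[1]]
    daily <- engineer_gi(build_daily_records(ind))
    lab <- code_behavior_days(ind$behavior, "BOTH")
    rows <- align_days(daily, lab)
    suppressWarnings(chisq.test(table(rows$constipation, rows$y))$p.value)
  }, numeric(1))
  ## p-values should look uniform, not concentrated at 0
  expect_lte(sum(pvals < 0.05), 2)
  expect_gt(max(pvals), 0.2)
})

test_that("missingness injection is an identity at zero rates", {
  cfg <- synth_config(n_individuals = 1, days_per_individual = 60,
                      loa_gap_rate = 0, time_sampling_rate = 0, seed = 6)
  co <- generate_cohort(cfg)
  expect_identical(inject_missingness(co, cfg), co)
})

test_that("LOA gaps blank resident sources and stay recoverable", {
  cfg <- synth_config(n_individuals = 1, days_per_individual = 200,
                      loa_gap_rate = 0.01, loa_gap_length = 7, seed = 8)
  co <- inject_missingness(generate_cohort(cfg), cfg)
  ind <- co$individuals[[1]]
  expect_gt(length(ind$loa_dates), 0)
  ## gap dates absent from sleep and BM sources
  expect_false(any(as.Date(ind$sleep$date) %in% ind$loa_dates))
  expect_false(any(as.Date(ind$bm$date) %in% ind$loa_dates))
  ## behavior shifts flagged missing, not deleted
  gap_rows <- as.Date(ind$behavior$date) %in% ind$loa_dates
  expect_true(all(ind$behavior$status[gap_rows] == "missing"))
  expect_equal(sum(gap_rows), 3 * length(ind$loa_dates))
  ## gap days are excluded downstream
  lab <- code_behavior_days(ind$behavior, "BOTH")
  expect_true(all(lab$label[lab$date %in% ind$loa_dates] == "excluded"))
})

test_that("universal time sampling excludes every behavior day downstream", {
  cfg <- synth_config(n_individuals = 1, days_per_individual = 40,
                      time_sampling_rate = 1, seed = 9)
  co <- inject_missingness(generate_cohort(cfg), cfg)
  ind <- co$individuals[[1]]
  lab <- code_behavior_days(ind$behavior, "BOTH")
  expect_true(all(lab$label == "excluded"))
  daily <- engineer_gi(build_daily_records(ind))
  expect_equal(nrow(align_days(daily, lab)), 0)
})

test_that("written cohorts round-trip through the CSV readers", {
  cfg <- synth_config(n_individuals = 1, days_per_individual = 50,
                      loa_gap_rate = 0.02, seed = 10)
  co <- inject_missingness(generate_cohort(cfg), cfg)
  dir <- file.path(tempdir(), "roundtrip")
  unlink(dir, recursive = TRUE)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(names(back$individuals), names(co$individuals))
  ind0 <- co$individuals[[1]]; ind1 <- back$individuals[[1]]
  expect_equal(as.Date(ind1$loa_dates), as.Date(ind0$loa_dates))
  expect_equal(ind1$meta$sex, ind0$meta$sex)
  ## cleaned daily records agree after the round trip
  d0 <- build_daily_records(ind0); d1 <- build_daily_records(ind1)
  expect_equal(d1$sleep_hours, d0$sleep_hours, tolerance = 1e-8)
  expect_equal(d1$bm_count, d0$bm_count)
  expect_equal(d1$moon_illum_pct, d0$moon_illum_pct, tolerance = 1e-8)
  ## truth round-trips with realized rates intact
  expect_equal(back$truth[[1]]$realized_rate, co$truth[[1]]$realized_rate)
})
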