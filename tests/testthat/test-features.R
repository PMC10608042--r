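test_that("behavior-day coding follows the at-least-one / exclusion rules", {
  tab <- make_shift_table(
    list(c("behavior", "none", "none"),
         c("none", "none", "missing"),
         c("behavior", "none", "none"),
         c("none", "time_sampled", "none"),
         c("none", "none", "none"),
         c("behavior", "behavior", "none")),
    list(c("AGG", "", ""),
         c("", "", ""),
         c("SIB", "", ""),
         c("", "", ""),
         c("", "", ""),
         c("SIB", "AGG", "")))
  agg <- code_behavior_days(tab, "AGG")
  expect_equal(agg$label,
               c("behavior", "excluded", "none", "excluded", "none", "behavior"))
  expect_equal(agg$exclusion_reason[2], "missing_shift")
  expect_equal(agg$exclusion_reason[4], "time_sampled")
  ## SIB-only day counts for SIB and BOTH but not AGG
  sib <- code_behavior_days(tab, "SIB")
  expect_equal(sib$label[3], "behavior")
  both <- code_behavior_days(tab, "BOTH")
  expect_equal(both$label[c(1, 3, 6)], rep("behavior", 3))
  ## malformed day (not exactly 3 shifts) is excluded with a warning
  expect_warning(bad <- code_behavior_days(tab[-1, ], "AGG"), "3 shift")
  expect_equal(bad$label[1], "excluded")
})

test_that("adding a behavior to a recorded shift never flips behavior to none", {
  set.seed(42)
  for (rep in 1:25) {
    st <- sample(c("behavior", "none"), 3, replace = TRUE)
    cat0 <- ifelse(st == "behavior", "AGG", "")
    tab <- make_shift_table(list(st), list(cat0))
    before <- code_behavior_days(tab, "AGG")$label
    ## upgrade one non-behavior shift
    idx <- which(st == "none")
    if (length(idx) == 0) next
    st2 <- st; st2[idx[1]] <- "behavior"
    cat2 <- ifelse(st2 == "behavior", "AGG", "")
    after <- code_behavior_days(make_shift_table(list(st2), list(cat2)), "AGG")$label
    expect_false(before == "behavior" && after == "none")
    expect_equal(after, "behavior")
  }
})

test_that("GI engineering reproduces the constipation/diarrhea/abnormal rules", {
  daily <- data.frame(
    date = as.Date("2020-01-01") + 0:4,
    bm_count = c(0, 5, 1, 2, 1),
    bristol_mean = c(0, 6, 4, NA, 2),
    bristol_min = c(0, 6, 4, NA, 2),
    bristol_max = c(0, 7, 4, NA, 2),
    bm_intervention = c(0, 0, 0, 0, 0))
  out <- engineer_gi(daily)
  ## no BMs: constipated and abnormal, not diarrhea
  expect_equal(out$constipation[1], 1)
  expect_equal(out$abnormal_bm[1], 1)
  expect_equal(out$diarrhea[1], 0)
  expect_equal(out$extreme_bristol_diff[1], 3.5)  # Bristol coded 0 on no-BM days
  ## 5 BMs with high Bristol: diarrhea and abnormal
  expect_equal(out$diarrhea[2], 1)
  expect_equal(out$abnormal_bm[2], 1)
  ## one ideal-range BM: all flags off, extreme diff |4 - 3.5|
  expect_equal(unlist(out[3, c("constipation", "diarrhea", "abnormal_bm")]),
               c(constipation = 0, diarrhea = 0, abnormal_bm = 0))
  expect_equal(out$extreme_bristol_diff[3], 0.5)
  ## BMs without Bristol: count clauses evaluable, extreme diff missing
  expect_equal(out$diarrhea[4], 0)
  expect_true(is.na(out$extreme_bristol_diff[4]))
  ## Bristol 2: constipation side
  expect_equal(out$constipation[5], 1)
})

test_that("constipation and diarrhea each imply an abnormal BM day", {
  set.seed(9)
  daily <- data.frame(
    date = as.Date("2020-01-01") + 0:199,
    bm_count = rpois(200, 1.5),
    bm_intervention = rbinom(200, 1, 0.1))
  b <- replicate(200, {
    n <- sample(0:3, 1)
    if (n == 0) c(0, 0) else range(sample(1:7, n, replace = TRUE))
  })
  daily$bristol_min <- ifelse(daily$bm_count == 0, 0, b[1, ])
  daily$bristol_max <- ifelse(daily$bm_count == 0, 0, b[2, ])
  daily$bristol_mean <- (daily$bristol_min + daily$bristol_max) / 2
  out <- engineer_gi(daily)
  expect_true(all(out$abnormal_bm[out$constipation == 1] == 1))
  expect_true(all(out$abnormal_bm[out$diarrhea == 1] == 1))
})

test_that("day alignment pairs day-d predictors with the day-(d+1) label", {
  dates <- as.Date("2020-01-01") + 0:4
  daily <- data.frame(date = dates, a = 1:5, b = c(10, 20, 30, 40, 50))
  labels <- data.frame(date = dates,
                       label = c("none", "behavior", "excluded", "none", "behavior"),
                       exclusion_reason = c("", "", "time_sampled", "", ""))
  out <- align_days(daily, labels, variables = c("a", "b"))
  ## d1 -> d2(behavior), d3 -> d4(none), d4 -> d5(behavior); d2 -> d3 excluded
  expect_equal(out$date, dates[c(1, 3, 4)])
  expect_equal(out$y, c(1L, 0L, 1L))
  expect_equal(attr(out, "n_candidate"), 3)
  ## a missing predictor drops the row and is counted
  daily$a[4] <- NA
  out2 <- align_days(daily, labels, variables = c("a", "b"))
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "n_dropped_missing"), 1)
  ## all labels excluded -> empty
  labels$label <- "excluded"
  expect_equal(nrow(align_days(daily, labels, variables = c("a", "b"))), 0)
})

test_that("alignment bookkeeping holds on a full synthetic individual", {
  m <- make_modeled_individual(mechanism = "null", base_rate = 0.4, days = 150,
                               seed = 3)
  expect_equal(nrow(m$rows),
               attr(m$rows, "n_candidate") - attr(m$rows, "n_dropped_missing"))
})

test_that("population standardization uses the divide-by-n convention", {
  rows <- data.frame(v = c(1, 2, 3), w = c(5, 5, 5), y = c(0, 1, 0))
  out <- standardize_rows(rows, variables = c("v", "w"))
  expect_equal(out$rows$v, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(mean(out$rows$v), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(out$rows$v^2)), 1, tolerance = 1e-9)
  ## constant variable dropped and reported
  expect_equal(out$dropped, "w")
  expect_false("w" %in% names(out$rows))
  ## re-standardizing is the identity
  out2 <- standardize_rows(out$rows, variables = "v")
  expect_equal(out2$rows$v, out$rows$v, tolerance = 1e-9)
  ## fewer than 2 rows aborts
  expect_error(standardize_rows(rows[1, ], variables = "v"), "at least 2")
})

test_that("pooled standardization centers the pooled population, not individuals", {
  r1 <- data.frame(v = c(0, 2), y = 0:1)
  r2 <- data.frame(v = c(10, 12), y = 0:1)
  out <- standardize_rows(list(a = r1, b = r2), variables = "v")
  pooled <- c(out$rows$a$v, out$rows$b$v)
  expect_equal(mean(pooled), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(pooled^2)), 1, tolerance = 1e-9)
  expect_true(all(out$rows$a$v < 0), all(out$rows$b$v > 0))
})
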