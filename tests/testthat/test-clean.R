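test_that("sleep hours are truncated to [0, 24] and bad entries flagged", {
  raw <- data.frame(date = as.Date("2020-01-01") + 0:3,
                    hours = c(26, -1, 7.5, 8.2),
                    interruptions = c(2, 0, 1, 3))
  out <- clean_sleep(raw)
  expect_equal(out$sleep_hours, c(24, 0, 7.5, 8.2))
  expect_equal(out$sleep_interruptions, c(2, 0, 1, 3))

  raw$hours <- c("26", "abc", "7.5", "8.2")
  expect_warning(out2 <- clean_sleep(raw), "non-numeric")
  expect_true(is.na(out2$sleep_hours[2]))
  expect_equal(out2$sleep_hours[c(1, 3, 4)], c(24, 7.5, 8.2))

  ## idempotence: cleaning cleaned output changes nothing
  expect_equal(clean_sleep(out), out)
})

test_that("BM events aggregate per day with validity and reporter rules", {
  d <- as.Date("2020-06-01")
  raw <- rbind(
    bm_row(d, bristol = 2), bm_row(d, bristol = 5),
    bm_row(d + 1, reporter = "parent", bristol = 4),
    bm_row(d + 2, bristol = NA, note = TRUE),
    bm_row(d + 3, bristol = NA, size = "", note = FALSE),  # invalid event
    bm_row(d + 4, record_type = "intervention"),
    bm_row(d + 4, bristol = 4)
  )
  out <- clean_bm(raw, observed_dates = d + 0:4)
  ## two scored events
  expect_equal(out$bm_count[1], 2)
  expect_equal(out$bristol_mean[1], 3.5)
  expect_equal(out$bristol_min[1], 2)
  expect_equal(out$bristol_max[1], 5)
  ## parent report dropped -> observed no-BM day, Bristol coded 0
  expect_equal(out$bm_count[2], 0)
  expect_equal(out$bristol_mean[2], 0)
  ## note-only valid event: counts, but Bristol aggregates unknowable
  expect_equal(out$bm_count[3], 1)
  expect_true(is.na(out$bristol_mean[3]))
  ## event with no bristol/size/note is invalid
  expect_equal(out$bm_count[4], 0)
  ## intervention flag
  expect_equal(out$bm_intervention, c(0, 0, 0, 0, 1))

  expect_warning(
    out5 <- clean_bm(rbind(bm_row(d, bristol = 9), bm_row(d, bristol = 3)), d),
    "outside 1..7")
  expect_equal(out5$bm_count, 1)
  expect_equal(out5$bristol_mean, 3)
})

test_that("no-BM runs beyond the 3-day buffer become missing", {
  mk <- function(counts, explicit = rep(FALSE, length(counts))) {
    data.frame(date = as.Date("2020-03-01") + seq_along(counts) - 1L,
               bm_count = counts, bristol_mean = ifelse(counts > 0, 4, 0),
               bristol_min = ifelse(counts > 0, 4, 0),
               bristol_max = ifelse(counts > 0, 4, 0),
               bm_intervention = 0, bm_explicit_no = explicit)
  }
  ## 3 no-BM days then a BM: nothing reclassified
  out <- apply_bm_buffer(mk(c(1, 0, 0, 0, 2)))
  expect_false(anyNA(out$bm_count))
  ## 6 no-BM days then a BM: days 4-6 of the run missing, BM day retained
  out <- apply_bm_buffer(mk(c(1, 0, 0, 0, 0, 0, 0, 2)))
  expect_equal(is.na(out$bm_count), c(F, F, F, F, T, T, T, F))
  expect_equal(out$bm_count[8], 2)
  ## explicit no-BM indications suspend the buffer
  out <- apply_bm_buffer(mk(c(1, 0, 0, 0, 0, 0, 0, 2), explicit = rep(TRUE, 8)))
  expect_false(anyNA(out$bm_count))
  ## every day has a BM: identity
  ident <- mk(rep(2, 6))
  expect_equal(apply_bm_buffer(ident), ident)
})

test_that("allergen series fill with zeros outside and LOCF inside the season", {
  yr <- as.Date("2020-01-01") + 0:365
  raw <- data.frame(date = as.Date(c("2020-04-10", "2020-04-14", "2020-08-02")),
                    tree = c(5, 9, 0), grass = c(1, 2, 3),
                    weed = c(0, 1, 7), total = c(8, 13, 11))
  out <- fill_allergen(raw, yr)
  at <- function(d) out[out$date == as.Date(d), ]
  expect_equal(at("2020-04-11")$allergen_tree, 5)   # LOCF
  expect_equal(at("2020-04-13")$allergen_tree, 5)
  expect_equal(at("2020-04-14")$allergen_tree, 9)
  expect_equal(at("2020-01-15")$allergen_total, 0)  # before first obs of year
  expect_equal(at("2020-08-03")$allergen_total, 0)  # after last obs of year
  expect_equal(at("2020-06-01")$allergen_total, 13) # LOCF of total
  ## total >= each category on observed days
  obs <- out[out$date %in% raw$date, ]
  expect_true(all(obs$allergen_total >= obs$allergen_tree))
})

test_that("weather quality flags discard individual values only", {
  raw <- data.frame(date = as.Date("2020-01-01") + 0:2,
                    tmax = c(85, 40, 33), tmin = c(60, 30, 20),
                    prcp = c(0, 0.5, 0.1), snow = c(0, 0, 2), snwd = c(0, 0, 4),
                    qflag_tmax = c("X", "", ""), qflag_tmin = "",
                    qflag_prcp = c("", "", "G"), qflag_snow = "", qflag_snwd = "")
  out <- clean_weather(raw)
  expect_true(is.na(out$tmax_f[1]))
  expect_equal(out$tmin_f[1], 60)        # per-value, not per-day
  expect_true(is.na(out$prcp_in[3]))
  expect_equal(out$tmax_f[3], 33)
  expect_equal(out$tmax_f[2], 40)        # all flags clear: identity
  ## idempotence: cleaned output has no flags and passes through
  expect_equal(clean_weather(out), out)
})

test_that("lunar conversions apply sentinels, day fractions, and whole days", {
  raw <- data.frame(date = as.Date("2020-05-01") + 0:1,
                    rise = c("12:00:00", ""), set = c("", "06:30:00"),
                    culmination = c("18:00:00", "03:00:00"),
                    distance_km = c(380000, 400000),
                    altitude_deg = c(25, -10), azimuth_deg = c(120, 240),
                    shadow_m = c(2.14, NA),
                    illum_pct = c(55.2, 99.1), age_days = c(7.38265, 14.77),
                    next_new = c("2020-05-04 16:48:00", "2020-05-22 07:00:00"),
                    next_full = c("2020-05-12 07:00:00", "2020-05-08 01:00:00"))
  out <- clean_moon(raw)
  expect_equal(out$moon_rise_frac[1], 0.5)                       # half day
  expect_equal(out$moon_rise_frac[2], 0)                         # no rise -> 00:00:00
  expect_equal(out$moon_set_frac[1], 86399 / 86400)              # no set -> 23:59:59
  expect_equal(out$moon_shadow_m, c(2.14, 0))                    # absent shadow -> 0
  expect_equal(out$days_to_new_moon[1], 3)                       # 3.7 days -> whole days
  expect_equal(out$days_to_full_moon[2], 6)
  expect_equal(out$moon_age_pct[1], 100 * 7.38265 / 29.530588)
  expect_true(all(out$moon_illum_pct >= 0 & out$moon_illum_pct <= 100))
})

test_that("daily record assembly is gap-free with explicit missing flags", {
  cfg <- synth_config(n_individuals = 1, days_per_individual = 60,
                      behavior_mechanism = "null", base_rate = 0.4,
                      loa_gap_rate = 0.05, loa_gap_length = 4, seed = 11)
  co <- inject_missingness(generate_cohort(cfg), cfg)
  ind <- co$individuals[[1]]
  daily <- build_daily_records(ind)
  expect_equal(as.numeric(diff(daily$date)), rep(1, nrow(daily) - 1))
  ## LOA days carry explicit NA in resident-collected sources
  if (length(ind$loa_dates) > 0) {
    gap <- daily[daily$date %in% ind$loa_dates, ]
    expect_true(all(is.na(gap$sleep_hours)))
    expect_true(all(is.na(gap$bm_count)))
  }
})
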