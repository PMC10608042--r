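## Synthetic multi-individual daily cohort generator.
##
## The generator states a world with the statistical structure the analysis
## assumes: heterogeneous per-individual behavior base rates, next-day
## behavior driven by prior-day engineered features (on the z-score scale
## the model sees), seasonal allergen series with station gaps, lunar
## variables on a 29.5-day cycle, occasional out-of-range sleep entries,
## and missingness from leaves of absence and time-sampled shifts.

#' Configuration for the synthetic cohort generator
#'
#' @param n_individuals number of individuals.
#' @param days_per_individual length of each daily series.
#' @param start_date first record date (admission is one month earlier, so
#'   the settle-in period ends as records begin).
#' @param behavior_mechanism `"logistic_additive"` (next-day behavior
#'   probability is logistic in a weighted sum of day-d standardized
#'   engineered features), `"xor_nonadditive"` (probability is high iff
#'   exactly one of two designated indicators — above-median sleep hours
#'   and above-median maximum temperature — is active; a minimal
#'   non-additive rule invisible to linear models), or `"null"` (labels
#'   independent of all predictors).
#' @param effect_weights named numeric vector of log-odds weights on the
#'   standardized engineered features (names must come from
#'   [reduced_variables()]); ignored under `"null"`.
#' @param base_rate target marginal behavior probability; the additive
#'   mechanism calibrates its intercept so the mean probability matches it.
#' @param xor_high,xor_low behavior probabilities when the XOR condition
#'   holds / fails (defaults 0.95 / 0.05).
#' @param loa_gap_rate per-day probability of starting a leave-of-absence
#'   gap.
#' @param loa_gap_length length of each gap in days.
#' @param time_sampling_rate per-shift probability of time-sampled
#'   collection (such days are later excluded).
#' @param female_fraction probability an individual is female.
#' @param agg_prob probability a behavior event is aggression (else
#'   self-injury).
#' @param seed integer master seed; every draw derives from it.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 5L,
                         days_per_individual = 400L,
                         start_date = as.Date("2016-01-01"),
                         behavior_mechanism = c("logistic_additive",
                                                "xor_nonadditive", "null"),
                         effect_weights = c(constipation = 1.5,
                                            sleep_hours = -1.0),
                         base_rate = 0.3,
                         xor_high = 0.95, xor_low = 0.05,
                         loa_gap_rate = 0, loa_gap_length = 7L,
                         time_sampling_rate = 0,
                         female_fraction = 0.2,
                         agg_prob = 0.7,
                         seed = 1L) {
  behavior_mechanism <- match.arg(behavior_mechanism)
  probs <- c(base_rate = base_rate, loa_gap_rate = loa_gap_rate,
             time_sampling_rate = time_sampling_rate,
             female_fraction = female_fraction, agg_prob = agg_prob,
             xor_high = xor_high, xor_low = xor_low)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  stopifnot(n_individuals >= 1L, days_per_individual >= 2L, loa_gap_length >= 1L)
  if (length(effect_weights) > 0L) {
    unknown <- setdiff(names(effect_weights), reduced_variables())
    if (length(unknown) > 0L) {
      stop("effect_weights reference unknown variable(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 days_per_individual = as.integer(days_per_individual),
                 start_date = as.Date(start_date),
                 behavior_mechanism = behavior_mechanism,
                 effect_weights = effect_weights,
                 base_rate = base_rate, xor_high = xor_high, xor_low = xor_low,
                 loa_gap_rate = loa_gap_rate,
                 loa_gap_length = as.integer(loa_gap_length),
                 time_sampling_rate = time_sampling_rate,
                 female_fraction = female_fraction, agg_prob = agg_prob,
                 seed = as.integer(seed)),
            class = "synth_config")
}

## raw source tables for one individual (complete; missingness injected later)
generate_sources <- function(config, dates, sex, bristol_shift) {
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  day_index <- seq_len(n) - 1L

  ## --- sleep (keyed by the evening date; the night runs into the next morning)
  hours <- stats::rnorm(n, 8, 1.2)
  corrupt <- stats::runif(n) < 0.01
  hours[corrupt] <- hours[corrupt] + sample(c(-12, 18), sum(corrupt), replace = TRUE)
  menses <- if (sex == "F") {
    phase <- sample.int(28L, 1L)
    as.numeric(((day_index + phase) %% 28L) < 4L)
  } else rep(0, n)
  sleep <- data.frame(date = dates, hours = round(hours, 1),
                      interruptions = stats::rpois(n, 1), menses = menses)

  ## --- bowel movements (event-level long table)
  n_ev <- stats::rpois(n, 1.1)
  rows <- list()
  for (i in seq_len(n)) {
    if (n_ev[i] > 0L) {
      bristol <- clamp(round(stats::rnorm(n_ev[i], 3.5 + bristol_shift, 1.3)), 1, 7)
      no_bristol <- stats::runif(n_ev[i]) < 0.07
      bristol[no_bristol] <- NA
      rows[[length(rows) + 1L]] <- data.frame(
        date = dates[i], record_type = "event",
        reporter = sample(c("staff", "nurse", "self", "hospital", "parent"),
                          n_ev[i], replace = TRUE,
                          prob = c(0.70, 0.14, 0.06, 0.06, 0.04)),
        bristol = bristol,
        size = ifelse(stats::runif(n_ev[i]) < 0.3,
                      sample(c("small", "medium", "large"), n_ev[i], replace = TRUE),
                      ""),
        note = no_bristol | stats::runif(n_ev[i]) < 0.3)
    } else if (stats::runif(1) < 0.8) {
      rows[[length(rows) + 1L]] <- data.frame(
        date = dates[i], record_type = "no_bm", reporter = "staff",
        bristol = NA_real_, size = "", note = FALSE)
    }
    if (stats::runif(1) < 0.08) {
      rows[[length(rows) + 1L]] <- data.frame(
        date = dates[i], record_type = "intervention", reporter = "nurse",
        bristol = NA_real_, size = "", note = FALSE)
    }
  }
  bm <- do.call(rbind, rows)

  ## --- allergen station (sparse, seasonal Apr 1 - Sep 30)
  in_season <- doy >= 91L & doy <= 273L
  observed <- in_season & stats::runif(n) < 0.7
  lam_tree <- 60 * exp(-((doy - 120) / 25)^2)
  lam_grass <- 30 * exp(-((doy - 170) / 30)^2)
  lam_weed <- 40 * exp(-((doy - 240) / 30)^2)
  tree <- stats::rpois(n, lam_tree)
  grass <- stats::rpois(n, lam_grass)
  weed <- stats::rpois(n, lam_weed)
  unid <- stats::rpois(n, 2)
  allergen <- data.frame(date = dates, tree = tree, grass = grass,
                         weed = weed, total = tree + grass + weed + unid)
  allergen <- allergen[observed, , drop = FALSE]

  ## --- weather station with per-value quality flags
  tmax <- 56 + 26 * sin(2 * pi * (doy - 110) / 365.25) + stats::rnorm(n, 0, 6)
  tmin <- tmax - stats::runif(n, 8, 20)
  wet <- stats::runif(n) < 0.35
  prcp <- ifelse(wet, round(stats::rexp(n, 4), 2), 0)
  snow <- ifelse(wet & tmax < 35, round(stats::runif(n, 0.5, 6), 1), 0)
  snwd <- ifelse(tmax < 32, round(stats::runif(n, 0, 10), 1), 0)
  flag <- function() ifelse(stats::runif(n) < 0.02, "G", "")
  weather <- data.frame(date = dates, tmax = round(tmax, 1),
                        tmin = round(tmin, 1), prcp = prcp, snow = snow,
                        snwd = snwd,
                        qflag_tmax = flag(), qflag_tmin = flag(),
                        qflag_prcp = flag(), qflag_snow = flag(),
                        qflag_snwd = flag())

  ## --- lunar ephemerides sampled at 07:00
  cyc <- 29.530588
  age <- (day_index + stats::runif(1, 0, cyc)) %% cyc
  illum <- 50 * (1 - cos(2 * pi * age / cyc))
  rise_sec <- (6 * 3600 + day_index * 3060) %% 86400
  set_sec <- (rise_sec + 12.4 * 3600) %% 86400
  culm_sec <- (rise_sec + 6.2 * 3600) %% 86400
  rise <- seconds_to_hms(rise_sec)
  sets <- seconds_to_hms(set_sec)
  no_rise <- stats::runif(n) < 0.03
  no_set <- stats::runif(n) < 0.03
  rise[no_rise] <- ""
  sets[no_set] <- ""
  altitude <- 30 * sin(2 * pi * age / cyc) + stats::rnorm(n, 0, 5)
  shadow <- ifelse(altitude > 5, round(1 / tan(pmax(altitude, 5) * pi / 180), 2),
                   NA_real_)
  shadow[illum < 2] <- NA_real_
  fmt_dt <- function(offset_days) {
    format(as.POSIXct(paste(dates, "07:00:00"), tz = "UTC") +
             round(offset_days * 86400), "%Y-%m-%d %H:%M:%S")
  }
  moon <- data.frame(date = dates,
                     rise = rise, set = sets,
                     culmination = seconds_to_hms(culm_sec),
                     distance_km = round(384400 + 20000 *
                                           sin(2 * pi * day_index / 27.55)),
                     altitude_deg = round(altitude, 2),
                     azimuth_deg = round(stats::runif(n, 90, 270), 2),
                     shadow_m = shadow,
                     illum_pct = round(illum, 2),
                     age_days = round(age, 3),
                     next_new = fmt_dt((cyc - age) %% cyc),
                     next_full = fmt_dt((cyc / 2 - age) %% cyc))

  list(sleep = sleep, bm = bm, allergen = allergen, weather = weather,
       moon = moon)
}

## standardized engineered day-d features for the label mechanism
synth_features <- function(sources, dates) {
  ind <- c(sources, list(behavior = data.frame(date = dates)))
  daily <- engineer_gi(build_daily_records(ind))
  z <- daily[match(dates, daily$date), reduced_variables(), drop = FALSE]
  for (v in names(z)) {
    x <- z[[v]]
    mu <- mean(x, na.rm = TRUE)
    sdev <- pop_sd(x[!is.na(x)])
    z[[v]] <- if (!is.finite(sdev) || sdev <= 1e-12) rep(0, length(x))
              else (x - mu) / sdev
    z[[v]][is.na(z[[v]])] <- 0  # latent mechanism uses the mean for gaps
  }
  z
}

calibrate_intercept <- function(lp, base_rate) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - base_rate
  stats::uniroot(f, interval = stats::qlogis(base_rate) + c(-25, 25))$root
}

#' Generate a synthetic multi-individual daily cohort
#'
#' Draws each individual's raw source tables first, computes the day-d
#' engineered features exactly as the cleaning/feature modules would (so
#' the generating weights live on the same standardized scale the model
#' sees), and then draws the day-(d+1) behavior label from the configured
#' mechanism.  Deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_cohort` with elements `individuals` (named
#'   list; each holds `behavior`, `sleep`, `bm`, `allergen`, `weather`,
#'   `moon`, `meta`, `loa_dates`) and `truth` (per-individual generating
#'   weights and realized behavior rate).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  shift_names <- c("07-15", "15-23", "23-07")
  individuals <- list()
  truth <- list()
  for (i in seq_len(config$n_individuals)) {
    id <- sprintf("ind%03d", i)
    sex <- if (stats::runif(1) < config$female_fraction) "F" else "M"
    bristol_shift <- stats::rnorm(1, 0, 0.5)
    age_at_start <- stats::runif(1, 10, 17.5)
    dates <- seq(config$start_date, by = "day",
                 length.out = config$days_per_individual)
    sources <- generate_sources(config, dates, sex, bristol_shift)
    z <- synth_features(sources, dates)

    mech <- config$behavior_mechanism
    n <- length(dates)
    p <- if (mech == "null") {
      rep(config$base_rate, n)
    } else if (mech == "logistic_additive") {
      w <- config$effect_weights
      lp <- if (length(w) > 0L) {
        as.numeric(as.matrix(z[, names(w), drop = FALSE]) %*% w)
      } else rep(0, n)
      stats::plogis(calibrate_intercept(lp, config$base_rate) + lp)
    } else {  # xor_nonadditive
      a <- z$sleep_hours > 0
      b <- z$tmax_f > 0
      ifelse(xor(a, b), config$xor_high, config$xor_low)
    }
    ## behavior on day d+1 is driven by day-d features; day 1 has no prior
    y <- integer(n)
    y[1L] <- stats::rbinom(1L, 1L, config$base_rate)
    y[2:n] <- stats::rbinom(n - 1L, 1L, p[seq_len(n - 1L)])

    behavior <- data.frame(
      date = rep(dates, each = 3L),
      shift = rep(shift_names, times = n),
      status = "none", category = "",
      stringsAsFactors = FALSE)
    for (d in which(y == 1L)) {
      hit_shift <- sample.int(3L, 1L)
      row <- (d - 1L) * 3L + hit_shift
      behavior$status[row] <- "behavior"
      behavior$category[row] <-
        if (stats::runif(1) < config$agg_prob) "AGG" else "SIB"
    }

    meta <- list(id = id, sex = sex, resident = TRUE, asd = TRUE,
                 admission = config$start_date - 31L,
                 age_at_start = age_at_start)
    individuals[[id]] <- list(behavior = behavior, sleep = sources$sleep,
                              bm = sources$bm, allergen = sources$allergen,
                              weather = sources$weather, moon = sources$moon,
                              meta = meta, loa_dates = as.Date(character()))
    truth[[id]] <- list(
      mechanism = mech,
      weights = if (mech == "logistic_additive") config$effect_weights
                else numeric(),
      realized_rate = mean(y), sex = sex)
  }
  structure(list(individuals = individuals, truth = truth, config = config),
            class = "synth_cohort")
}

#' Inject leave-of-absence gaps and time-sampled shifts
#'
#' Contiguous LOA gaps blank the resident-collected sources for the gap
#' days (behavior shifts become `missing`, sleep and BM rows are removed);
#' the gap dates remain recoverable on each individual as `loa_dates`.
#' Independently, random shifts are re-marked as collected by time
#' sampling.  External station series (allergen, weather, moon) are not
#' affected by a resident's absence.
#'
#' @param cohort a `synth_cohort`.
#' @param config the same [synth_config()] (uses `loa_gap_rate`,
#'   `loa_gap_length`, `time_sampling_rate`, `seed`).
#' @return the modified `synth_cohort`.
#' @export
inject_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "synth_cohort"), inherits(config, "synth_config"))
  if (config$loa_gap_rate == 0 && config$time_sampling_rate == 0) return(cohort)
  set.seed(derive_seed(config$seed, 555L))
  for (id in names(cohort$individuals)) {
    ind <- cohort$individuals[[id]]
    dates <- sort(unique(as.Date(ind$behavior$date)))
    loa <- as.Date(character())
    d <- 1L
    while (d <= length(dates)) {
      if (stats::runif(1) < config$loa_gap_rate) {
        gap <- dates[d:min(d + config$loa_gap_length - 1L, length(dates))]
        loa <- c(loa, gap)
        d <- d + config$loa_gap_length
      } else {
        d <- d + 1L
      }
    }
    if (length(loa) > 0L) {
      in_gap <- as.Date(ind$behavior$date) %in% loa
      ind$behavior$status[in_gap] <- "missing"
      ind$behavior$category[in_gap] <- ""
      ind$sleep <- ind$sleep[!(as.Date(ind$sleep$date) %in% loa), , drop = FALSE]
      ind$bm <- ind$bm[!(as.Date(ind$bm$date) %in% loa), , drop = FALSE]
    }
    if (config$time_sampling_rate > 0) {
      ts <- ind$behavior$status != "missing" &
        stats::runif(nrow(ind$behavior)) < config$time_sampling_rate
      ind$behavior$status[ts] <- "time_sampled"
      ind$behavior$category[ts] <- ""
    }
    ind$loa_dates <- as.Date(loa)
    cohort$individuals[[id]] <- ind
  }
  cohort
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individual(s), %d days each, mechanism %s\n",
              length(x$individuals), x$config$days_per_individual,
              x$config$behavior_mechanism))
  rates <- vapply(x$truth, function(t) t$realized_rate, numeric(1))
  cat(sprintf("  realized behavior rates: %s\n",
              paste(sprintf("%.2f", rates), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' One sub-directory per individual holding `behavior.csv`, `sleep.csv`,
#' `bm.csv`, `allergen.csv`, `weather.csv`, `moon.csv`, and `meta.json`
#' (including any LOA dates), plus a top-level `truth.json`.  Dates are
#' ISO-8601; the column dialects are documented in the packaged data
#' dictionary (`system.file("extdata", "data-dictionary.md", package =
#' "behaviorcast")`).
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (id in names(cohort$individuals)) {
    ind <- cohort$individuals[[id]]
    idir <- file.path(dir, id)
    dir.create(idir, showWarnings = FALSE)
    for (s in c("behavior", "sleep", "bm", "allergen", "weather", "moon")) {
      f <- file.path(idir, paste0(s, ".csv"))
      utils::write.csv(ind[[s]], f, row.names = FALSE)
      files <- c(files, f)
    }
    meta <- ind$meta
    meta$admission <- as.character(meta$admission)
    meta$loa_dates <- as.character(ind$loa_dates)
    f <- file.path(idir, "meta.json")
    jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' The reader validates that every expected source file is present and
#' re-types dates; the same dialect accommodates externally prepared data
#' laid out the same way.
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `synth_cohort` (with `truth` when `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(ids) == 0L) stop("no individual sub-directories under ", dir)
  individuals <- list()
  for (id in ids) {
    idir <- file.path(dir, id)
    ind <- list()
    for (s in c("behavior", "sleep", "bm", "allergen", "weather", "moon")) {
      f <- file.path(idir, paste0(s, ".csv"))
      if (!file.exists(f)) stop("missing source file: ", f)
      tab <- utils::read.csv(f, stringsAsFactors = FALSE)
      tab$date <- as.Date(tab$date)
      ind[[s]] <- tab
    }
    meta <- jsonlite::read_json(file.path(idir, "meta.json"), simplifyVector = TRUE)
    ind$loa_dates <- as.Date(unlist(meta$loa_dates) %||% character())
    meta$loa_dates <- NULL
    meta$admission <- as.Date(meta$admission)
    ind$meta <- meta
    individuals[[id]] <- ind
  }
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(individuals = individuals, truth = truth, config = NULL),
            class = "synth_cohort")
}
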