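## Source-specific cleaning of raw daily tables.
##
## Each cleaner takes one raw source table (the dialect written by
## `write_cohort()` and documented in inst/extdata/data-dictionary.md) and
## returns per-day columns with explicit NA for missing values.  No cleaner
## fabricates an observed value except through the documented fill rules
## (allergen zero/LOCF fills, lunar rise/set sentinels).

#' Clean nightly sleep records
#'
#' Sleep duration is clamped to \[0, 24\] hours; interruption counts are
#' rounded to non-negative integers.  Non-numeric entries become missing
#' with a warning rather than aborting the run.
#'
#' @param raw data frame with columns `date`, `hours`, `interruptions` and
#'   optionally `menses` (0/1/NA).  Already-cleaned output (columns
#'   `sleep_hours`, `sleep_interruptions`) is accepted unchanged, so the
#'   cleaner is idempotent.
#' @return data frame with columns `date`, `sleep_hours`,
#'   `sleep_interruptions`, `menses`.
#' @export
clean_sleep <- function(raw) {
  stopifnot(is.data.frame(raw), "date" %in% names(raw))
  hours <- raw[["hours"]] %||% raw[["sleep_hours"]]
  ints  <- raw[["interruptions"]] %||% raw[["sleep_interruptions"]]
  if (is.null(hours)) stop("sleep table lacks an hours column")
  to_num <- function(x, what) {
    if (is.numeric(x)) return(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "" & is.na(out)
    if (any(bad)) {
      warning(sprintf("%d non-numeric %s entr%s set to missing", sum(bad),
                      what, if (sum(bad) == 1L) "y" else "ies"), call. = FALSE)
    }
    out
  }
  hours <- clamp(to_num(hours, "sleep-hours"), 0, 24)
  ints <- to_num(ints %||% rep(NA_real_, nrow(raw)), "sleep-interruption")
  ints <- pmax(round(ints), 0)
  menses <- raw[["menses"]] %||% rep(NA_real_, nrow(raw))
  data.frame(date = as.Date(raw$date),
             sleep_hours = hours,
             sleep_interruptions = ints,
             menses = as.numeric(menses))
}

#' Clean and aggregate bowel-movement event records
#'
#' Applies the validity rules for BM events and aggregates them to one row
#' per observed day:
#' * parent-reported events are dropped (the resident is assumed absent);
#' * a valid event must carry a Bristol score, a size, or a staff note;
#' * Bristol scores outside 1..7 drop the event with a warning;
#' * valid events without a Bristol score count toward `bm_count` but not
#'   toward the mean/min/max Bristol aggregates;
#' * observed days with no BM are coded Bristol 0 (mean = min = max = 0);
#' * any intervention record (laxative, medication, prune/fluid intake) on
#'   a day sets the single binary `bm_intervention`.
#'
#' @param raw event-level data frame with columns `date`, `record_type`
#'   (`"event"`, `"no_bm"`, or `"intervention"`), `reporter`, `bristol`,
#'   `size`, `note` (logical/0-1).
#' @param observed_dates `Date` vector of days on which the resident was
#'   present and BM observation occurred.  An explicit `no_bm` marker row
#'   distinguishes a confirmed no-BM day from a merely unrecorded one; this
#'   distinction drives [apply_bm_buffer()].
#' @return data frame keyed by `observed_dates` with columns `bm_count`,
#'   `bristol_mean`, `bristol_min`, `bristol_max`, `bm_intervention`,
#'   `bm_explicit_no` (logical).
#' @export
clean_bm <- function(raw, observed_dates) {
  stopifnot(is.data.frame(raw))
  observed_dates <- sort(unique(as.Date(observed_dates)))
  if (nrow(raw) == 0L) {
    raw <- data.frame(date = as.Date(character()), record_type = character(),
                      reporter = character(), bristol = numeric(),
                      size = character(), note = logical())
  }
  raw$date <- as.Date(raw$date)
  ev <- raw[raw$record_type == "event", , drop = FALSE]
  ev <- ev[!(ev$reporter %in% "parent"), , drop = FALSE]
  bristol <- suppressWarnings(as.numeric(ev$bristol))
  bad_bristol <- !is.na(bristol) & (bristol < 1 | bristol > 7)
  if (any(bad_bristol)) {
    warning(sprintf("%d BM event(s) with Bristol outside 1..7 dropped",
                    sum(bad_bristol)), call. = FALSE)
    ev <- ev[!bad_bristol, , drop = FALSE]
    bristol <- bristol[!bad_bristol]
  }
  has_size <- !is.na(ev$size) & nzchar(as.character(ev$size))
  has_note <- !is.na(ev$note) & as.logical(ev$note)
  valid <- !is.na(bristol) | has_size | has_note
  ev <- ev[valid, , drop = FALSE]
  bristol <- bristol[valid]

  iv_dates <- unique(raw$date[raw$record_type == "intervention"])
  nobm_dates <- unique(raw$date[raw$record_type == "no_bm"])

  agg <- function(d) {
    sel <- ev$date == d
    b <- bristol[sel]
    b <- b[!is.na(b)]
    n <- sum(sel)
    if (n == 0L) {
      ## observed day without any valid BM: Bristol coded as 0
      c(count = 0, mean = 0, min = 0, max = 0)
    } else if (length(b) == 0L) {
      ## note/size-only events: count known, Bristol aggregates unknowable
      c(count = n, mean = NA_real_, min = NA_real_, max = NA_real_)
    } else {
      c(count = n, mean = mean(b), min = min(b), max = max(b))
    }
  }
  m <- t(vapply(observed_dates, agg, numeric(4)))
  data.frame(date = observed_dates,
             bm_count = m[, "count"],
             bristol_mean = m[, "mean"],
             bristol_min = m[, "min"],
             bristol_max = m[, "max"],
             bm_intervention = as.numeric(observed_dates %in% iv_dates),
             bm_explicit_no = observed_dates %in% nobm_dates)
}

#' Apply the 3-day no-BM observation buffer
#'
#' BMs were sometimes only recorded when an event occurred, so a long run of
#' observed days without any BM and without an explicit no-BM indication is
#' treated as unrecorded rather than as true absence: after more than 3
#' consecutive such days, days from the 4th onward become missing until the
#' next recorded BM (or explicitly indicated no-BM day).
#'
#' @param daily output of [clean_bm()], date-continuous over observed days.
#' @return `daily` with the buffered days' BM columns set to `NA`.
#' @export
apply_bm_buffer <- function(daily) {
  stopifnot(is.data.frame(daily), all(c("bm_count", "bm_explicit_no") %in% names(daily)))
  run <- 0L
  drop <- logical(nrow(daily))
  ord <- order(daily$date)
  for (i in ord) {
    cnt <- daily$bm_count[i]
    if (is.na(cnt)) next
    if (cnt == 0 && !isTRUE(daily$bm_explicit_no[i])) {
      run <- run + 1L
      if (run > 3L) drop[i] <- TRUE
    } else {
      run <- 0L
    }
  }
  cols <- c("bm_count", "bristol_mean", "bristol_min", "bristol_max", "bm_intervention")
  daily[drop, cols] <- NA_real_
  daily
}

#' Fill sparse allergen station series to a daily axis
#'
#' Pollen stations do not report every day.  Within each calendar year,
#' days before the first recorded observation and after the last are filled
#' with zeros; gaps between observations carry the previous valid
#' observation forward (LOCF).
#'
#' @param raw data frame with columns `date`, `tree`, `grass`, `weed`,
#'   `total` holding observed counts (total = tree + grass + weed +
#'   unidentified, so `total >= tree, grass, weed` on observed days).
#' @param dates full daily `Date` axis to fill.
#' @return data frame with columns `date`, `allergen_tree`,
#'   `allergen_grass`, `allergen_weed`, `allergen_total`.
#' @export
fill_allergen <- function(raw, dates) {
  dates <- sort(as.Date(dates))
  cats_in <- c("tree", "grass", "weed", "total")
  cats_out <- paste0("allergen_", cats_in)
  out <- data.frame(date = dates)
  if (is.null(raw) || nrow(raw) == 0L) {
    for (cc in cats_out) out[[cc]] <- 0
    return(out)
  }
  ## accept already-filled output (idempotence)
  if (all(cats_out %in% names(raw)) && !all(cats_in %in% names(raw))) {
    names(raw)[match(cats_out, names(raw))] <- cats_in
  }
  raw$date <- as.Date(raw$date)
  raw <- raw[order(raw$date), , drop = FALSE]
  for (k in seq_along(cats_in)) {
    vals <- rep(NA_real_, length(dates))
    obs <- raw[!is.na(raw[[cats_in[k]]]), c("date", cats_in[k])]
    for (yr in unique(format(dates, "%Y"))) {
      in_year <- format(dates, "%Y") == yr
      oy <- obs[format(obs$date, "%Y") == yr, , drop = FALSE]
      if (nrow(oy) == 0L) {
        vals[in_year] <- 0
        next
      }
      first_obs <- min(oy$date); last_obs <- max(oy$date)
      for (i in which(in_year)) {
        d <- dates[i]
        if (d < first_obs || d > last_obs) {
          vals[i] <- 0
        } else {
          prev <- oy[oy$date <= d, , drop = FALSE]
          vals[i] <- prev[[2L]][nrow(prev)]  # LOCF
        }
      }
    }
    out[[cats_out[k]]] <- vals
  }
  out
}

#' Clean weather station values using quality flags
#'
#' Each of the five core values (TMAX, TMIN in degrees F; PRCP, SNOW, SNWD
#' in inches) carries its own station quality flag; a raised flag discards
#' that value for that day.  Flags attach per value, so an unflagged TMAX is
#' retained even when PRCP is flagged.
#'
#' @param raw data frame with columns `date`, `tmax`, `tmin`, `prcp`,
#'   `snow`, `snwd` and optional flag columns `qflag_tmax`, ... (non-empty
#'   string = raised).  Cleaned output (no flag columns) passes through.
#' @return data frame with columns `date`, `tmax_f`, `tmin_f`, `prcp_in`,
#'   `snow_in`, `snwd_in`.
#' @export
clean_weather <- function(raw) {
  stopifnot(is.data.frame(raw), "date" %in% names(raw))
  vars_in <- c("tmax", "tmin", "prcp", "snow", "snwd")
  vars_out <- c("tmax_f", "tmin_f", "prcp_in", "snow_in", "snwd_in")
  out <- data.frame(date = as.Date(raw$date))
  for (k in seq_along(vars_in)) {
    v <- raw[[vars_in[k]]] %||% raw[[vars_out[k]]]
    v <- suppressWarnings(as.numeric(v))
    fl <- raw[[paste0("qflag_", vars_in[k])]]
    if (!is.null(fl)) v[!is.na(fl) & nzchar(as.character(fl))] <- NA_real_
    out[[vars_out[k]]] <- v
  }
  out
}

#' Clean lunar ephemeris records
#'
#' The raw table is sampled once per day at 07:00 local time.  Cleaning
#' applies the conversions used downstream:
#' * a moon rise that did not occur that day is recorded as `00:00:00`, a
#'   moon set that did not occur as `23:59:59`;
#' * all times become fractions of an 86400-second day;
#' * an absent shadow length (no shadow cast) becomes 0 m;
#' * the phase is reduced to the illumination percentage;
#' * moon age in days becomes a percentage of the 29.530588-day cycle;
#' * next new/full moon datetimes become whole-day differences from the
#'   record date (time of day not accounted for).
#'
#' @param raw data frame with columns `date`, `rise`, `set`, `culmination`
#'   (times `"HH:MM:SS"`, empty/NA = did not occur), `distance_km`,
#'   `altitude_deg`, `azimuth_deg`, `shadow_m`, `illum_pct`, `age_days`,
#'   `next_new`, `next_full` (ISO datetimes).
#' @return data frame of the cleaned lunar columns.
#' @export
clean_moon <- function(raw) {
  stopifnot(is.data.frame(raw), "date" %in% names(raw))
  date <- as.Date(raw$date)
  frac_of_day <- function(x, sentinel) {
    s <- hms_to_seconds(x)
    s[is.na(s)] <- sentinel
    s / 86400
  }
  days_to <- function(x) {
    d <- as.Date(substr(as.character(x), 1, 10))
    as.integer(d - date)
  }
  shadow <- suppressWarnings(as.numeric(raw$shadow_m))
  shadow[is.na(shadow)] <- 0
  data.frame(
    date = date,
    moon_illum_pct = clamp(suppressWarnings(as.numeric(raw$illum_pct)), 0, 100),
    moon_rise_frac = frac_of_day(raw$rise, 0),
    moon_set_frac = frac_of_day(raw$set, hms_to_seconds("23:59:59")),
    moon_culmination_frac = frac_of_day(raw$culmination, NA_real_),
    moon_distance_km = suppressWarnings(as.numeric(raw$distance_km)),
    moon_altitude_deg = suppressWarnings(as.numeric(raw$altitude_deg)),
    moon_azimuth_deg = suppressWarnings(as.numeric(raw$azimuth_deg)),
    moon_shadow_m = pmax(shadow, 0),
    moon_age_pct = 100 * suppressWarnings(as.numeric(raw$age_days)) / 29.530588,
    days_to_new_moon = days_to(raw$next_new),
    days_to_full_moon = days_to(raw$next_full)
  )
}

#' Assemble one gap-free daily record stream for an individual
#'
#' Runs every source cleaner and merges the results onto a single
#' continuous date axis spanning the individual's covered period.  Days a
#' source did not cover carry explicit `NA`s.  BM observation days are the
#' axis minus leave-of-absence dates; the 3-day no-BM buffer is applied.
#'
#' @param ind one individual's raw tables as produced by [generate_cohort()]
#'   or [read_cohort()]: a list with elements `behavior`, `sleep`, `bm`,
#'   `allergen`, `weather`, `moon`, and optionally `loa_dates`.
#' @return data frame keyed by `date` with all cleaned per-day columns.
#' @export
build_daily_records <- function(ind) {
  stopifnot(is.list(ind))
  all_dates <- as.Date(character())
  for (s in c("behavior", "sleep", "bm", "weather", "moon")) {
    if (!is.null(ind[[s]]) && nrow(ind[[s]]) > 0L) {
      all_dates <- c(all_dates, as.Date(ind[[s]]$date))
    }
  }
  if (length(all_dates) == 0L) stop("individual has no dated records")
  axis <- seq(min(all_dates), max(all_dates), by = "day")
  out <- data.frame(date = axis)

  loa <- as.Date(ind$loa_dates %||% character())
  observed <- axis[!(axis %in% loa)]

  sleep <- clean_sleep(ind$sleep)
  bm <- apply_bm_buffer(clean_bm(ind$bm, observed))
  allergen <- fill_allergen(ind$allergen, axis)
  weather <- clean_weather(ind$weather)
  moon <- clean_moon(ind$moon)

  for (tab in list(sleep, bm, allergen, weather, moon)) {
    idx <- match(out$date, tab$date)
    for (cc in setdiff(names(tab), "date")) out[[cc]] <- tab[[cc]][idx]
  }
  out$bm_explicit_no <- NULL
  out
}
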