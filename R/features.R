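## Behavior-day coding, engineered GI features, prior-day alignment, and
## population standardization.

#' The reduced predictor set used for modeling
#'
#' One representative variable was retained per environmental category
#' (total allergen count, maximum temperature, lunar illumination
#' percentage) alongside the GI, menses, and sleep variables.
#'
#' @return character vector of the 15 model variable names.
#' @export
reduced_variables <- function() {
  c("bm_count", "bristol_mean", "bristol_min", "bristol_max",
    "bm_intervention", "constipation", "diarrhea", "abnormal_bm",
    "extreme_bristol_diff", "menses", "sleep_hours", "sleep_interruptions",
    "allergen_total", "tmax_f", "moon_illum_pct")
}

#' Code each day as behavior / no-behavior / excluded
#'
#' A day counts as a behavior day if at least one recorded shift shows a
#' behavior of the target category, and as a no-behavior day if all recorded
#' shifts show none.  A day is excluded when any shift was collected by time
#' sampling (incompatible recording method) or when any shift is missing
#' (leave of absence or unrecorded data).
#'
#' @param shifts data frame with columns `date`, `shift` (one of
#'   `"07-15"`, `"15-23"`, `"23-07"`), `status` (one of `"behavior"`,
#'   `"none"`, `"missing"`, `"time_sampled"`), `category` (`"AGG"`,
#'   `"SIB"`, or `""`; non-empty iff status is behavior).
#' @param target `"AGG"`, `"SIB"`, or `"BOTH"` (either category counts).
#' @return data frame with columns `date`, `label` (`"behavior"`,
#'   `"none"`, `"excluded"`), `exclusion_reason` (`"time_sampled"`,
#'   `"missing_shift"`, or `""`).
#' @export
code_behavior_days <- function(shifts, target = c("AGG", "SIB", "BOTH")) {
  target <- match.arg(target)
  stopifnot(is.data.frame(shifts),
            all(c("date", "shift", "status") %in% names(shifts)))
  shifts$date <- as.Date(shifts$date)
  cat_col <- shifts[["category"]] %||% rep("", nrow(shifts))
  dates <- sort(unique(shifts$date))
  lab <- character(length(dates))
  reason <- character(length(dates))
  bad_days <- 0L
  for (i in seq_along(dates)) {
    sel <- shifts$date == dates[i]
    st <- shifts$status[sel]
    cats <- cat_col[sel]
    if (length(st) != 3L) {
      lab[i] <- "excluded"; reason[i] <- "missing_shift"
      bad_days <- bad_days + 1L
      next
    }
    if (any(st == "time_sampled")) {
      lab[i] <- "excluded"; reason[i] <- "time_sampled"
    } else if (any(st == "missing")) {
      lab[i] <- "excluded"; reason[i] <- "missing_shift"
    } else {
      hit <- st == "behavior" &
        (if (target == "BOTH") cats %in% c("AGG", "SIB") else
           vapply(strsplit(cats, "\\+"), function(p) target %in% p, logical(1)))
      lab[i] <- if (any(hit)) "behavior" else "none"
      reason[i] <- ""
    }
  }
  if (bad_days > 0L) {
    warning(sprintf("%d day(s) without exactly 3 shift entries excluded", bad_days),
            call. = FALSE)
  }
  data.frame(date = dates, label = lab, exclusion_reason = reason)
}

#' Engineer day-level gastrointestinal features
#'
#' From the cleaned BM columns, derives the binary flags
#' * `constipation`: min Bristol below 3, no BM that day, or a BM
#'   intervention that day;
#' * `diarrhea`: more than 3 BMs, or max Bristol above 5;
#' * `abnormal_bm`: a Bristol on either abnormal side, more than 3 BMs, no
#'   BMs, or an intervention;
#'
#' and the continuous `extreme_bristol_diff`, the largest distance of the
#' day's min/max Bristol from the optimal point 3.5.  No-BM days carry
#' Bristol 0, so their extreme difference is 3.5.  Days with BMs but no
#' Bristol information evaluate only the count/intervention clauses and
#' leave `extreme_bristol_diff` missing.
#'
#' @param daily data frame with columns `bm_count`, `bristol_mean`,
#'   `bristol_min`, `bristol_max`, `bm_intervention` (NA = missing day).
#' @return `daily` with the four engineered columns appended.
#' @export
engineer_gi <- function(daily) {
  stopifnot(is.data.frame(daily),
            all(c("bm_count", "bristol_min", "bristol_max", "bm_intervention")
                %in% names(daily)))
  cnt <- daily$bm_count
  bmin <- daily$bristol_min
  bmax <- daily$bristol_max
  iv <- daily$bm_intervention
  no_bm <- !is.na(cnt) & cnt == 0
  has_b <- !is.na(bmin)
  ## logical OR that treats NA-with-any-TRUE as TRUE, all-unknown as the
  ## known clauses only (count/intervention clauses still evaluable)
  con <- (has_b & bmin < 3) | no_bm | (!is.na(iv) & iv > 0)
  dia <- (!is.na(cnt) & cnt > 3) | (has_b & bmax > 5)
  abn <- (has_b & (bmin < 3 | bmax > 5)) | (!is.na(cnt) & cnt > 3) | no_bm |
    (!is.na(iv) & iv > 0)
  miss <- is.na(cnt)
  con[miss] <- NA; dia[miss] <- NA; abn[miss] <- NA
  daily$constipation <- as.numeric(con)
  daily$diarrhea <- as.numeric(dia)
  daily$abnormal_bm <- as.numeric(abn)
  daily$extreme_bristol_diff <-
    ifelse(has_b, pmax(abs(bmin - 3.5), abs(bmax - 3.5)), NA_real_)
  daily
}

#' Pair day-d predictors with the day-(d+1) behavior label
#'
#' Implements the one-day prediction alignment: the behavior day starts at
#' 07:00, the sleep row keyed to date d is the night running into the
#' morning of d+1, BM/weather/allergen cover calendar day d, and the lunar
#' record is sampled at 07:00 on day d.  Rows whose day-(d+1) label is
#' excluded, or whose predictor vector has any missing component, are
#' dropped; the counts are recorded as attributes `n_candidate` and
#' `n_dropped_missing`.
#'
#' @param daily engineered daily records ([build_daily_records()] +
#'   [engineer_gi()]).
#' @param labels output of [code_behavior_days()].
#' @param variables predictor columns to use (default [reduced_variables()]).
#' @return data frame with `date` (day d), the predictor columns, and the
#'   binary `y` (behavior on day d+1); zero rows if nothing aligns.
#' @export
align_days <- function(daily, labels, variables = reduced_variables()) {
  stopifnot(is.data.frame(daily), is.data.frame(labels))
  missing_vars <- setdiff(variables, names(daily))
  if (length(missing_vars) > 0L) {
    stop("daily records lack predictor column(s): ",
         paste(missing_vars, collapse = ", "))
  }
  daily$date <- as.Date(daily$date)
  labels$date <- as.Date(labels$date)
  next_lab <- labels$label[match(daily$date + 1L, labels$date)]
  keep <- !is.na(next_lab) & next_lab %in% c("behavior", "none")
  n_candidate <- sum(keep)
  x <- daily[keep, c("date", variables), drop = FALSE]
  y <- as.integer(next_lab[keep] == "behavior")
  complete <- stats::complete.cases(x[, variables, drop = FALSE])
  out <- x[complete, , drop = FALSE]
  out$y <- y[complete]
  rownames(out) <- NULL
  attr(out, "n_candidate") <- n_candidate
  attr(out, "n_dropped_missing") <- n_candidate - nrow(out)
  out
}

#' Z-score standardize predictors over the pooled population
#'
#' All variables, categorical and continuous alike, are standardized with
#' the population (divide-by-n) mean and standard deviation computed over
#' the rows of every included individual pooled together.  Zero-variance
#' variables are dropped and reported.
#'
#' @param rows list of per-individual feature data frames (from
#'   [align_days()]) or a single data frame.
#' @param variables predictor columns to standardize.
#' @return list with `rows` (same shape as input, standardized), `params`
#'   (data frame `variable`, `mean`, `sd`), and `dropped` (character vector
#'   of zero-variance variables, removed from `rows`).
#' @export
standardize_rows <- function(rows, variables = NULL) {
  single <- is.data.frame(rows)
  if (single) rows <- list(rows)
  stopifnot(length(rows) >= 1L, all(vapply(rows, is.data.frame, logical(1))))
  variables <- variables %||%
    setdiff(names(rows[[1L]]), c("date", "y", "individual"))
  pooled <- do.call(rbind, lapply(rows, function(r) r[, variables, drop = FALSE]))
  if (nrow(pooled) < 2L) stop("standardization needs at least 2 pooled rows")
  mu <- vapply(pooled, mean, numeric(1))
  sdev <- vapply(pooled, pop_sd, numeric(1))
  dropped <- variables[sdev <= 1e-12]
  kept <- setdiff(variables, dropped)
  rows <- lapply(rows, function(r) {
    for (v in kept) r[[v]] <- (r[[v]] - mu[[v]]) / sdev[[v]]
    r[, setdiff(names(r), dropped), drop = FALSE]
  })
  list(rows = if (single) rows[[1L]] else rows,
       params = data.frame(variable = kept, mean = unname(mu[kept]),
                           sd = unname(sdev[kept])),
       dropped = dropped)
}
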