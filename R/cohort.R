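## Cohort inclusion cascade and per-target cohort assignment.

#' Determine an individual's data-collection start date
#'
#' A one-month settling-in period follows admission; if behavior, sleep, or
#' GI collection started later than that, the latest of the first record
#' dates is used instead: start = max(admission + 1 month, first behavior,
#' first sleep, first GI record).
#'
#' @param admission admission `Date`.
#' @param first_behavior,first_sleep,first_gi first record `Date` of each
#'   source; `NA`/`NULL` means the source never started and excludes the
#'   individual.
#' @return the start `Date`.
#' @export
determine_start <- function(admission, first_behavior, first_sleep, first_gi) {
  firsts <- list(behavior = first_behavior, sleep = first_sleep, gi = first_gi)
  absent <- vapply(firsts, function(x) is.null(x) || is.na(x), logical(1))
  if (any(absent)) {
    stop("no records for source(s): ", paste(names(firsts)[absent], collapse = ", "),
         "; individual excluded")
  }
  max(add_months(as.Date(admission), 1L),
      as.Date(first_behavior), as.Date(first_sleep), as.Date(first_gi))
}

#' Evaluate the inclusion criteria for one individual and target
#'
#' Criteria, applied in cascade order: residency at the facility, age below
#' 19 years at the individual's data start, a confirmed ASD diagnosis, at
#' least 20 model-ready data points, and a maximum class imbalance of 90%
#' (an individual whose majority class exceeds 0.90 of days is excluded;
#' exactly 0.90 passes).
#'
#' @param meta list with elements `id`, `resident` (flag), `asd` (flag),
#'   `age_at_start` (years).
#' @param rows model-ready rows ([align_days()]) for this target, already
#'   truncated to at most 18 months from the start date.
#' @return list of class `inclusion_report`: `id`, `passed`,
#'   `failed_criteria`, `n_rows`, `majority_fraction`.
#' @export
apply_inclusion <- function(meta, rows) {
  stopifnot(is.list(meta), !is.null(meta$id))
  n <- nrow(rows)
  maj <- if (n > 0L) max(mean(rows$y), 1 - mean(rows$y)) else NA_real_
  failed <- character()
  if (!isTRUE(as.logical(meta$resident %||% TRUE))) failed <- c(failed, "residency")
  if ((meta$age_at_start %||% 0) >= 19) failed <- c(failed, "age")
  if (!isTRUE(as.logical(meta$asd %||% TRUE))) failed <- c(failed, "asd_diagnosis")
  if (n < 20L) failed <- c(failed, "min_points")
  if (!is.na(maj) && maj > 0.90) failed <- c(failed, "imbalance")
  structure(list(id = meta$id, passed = length(failed) == 0L,
                 failed_criteria = failed, n_rows = n,
                 majority_fraction = maj),
            class = "inclusion_report")
}

#' Assign individuals to the AGG, SIB, and BOTH cohorts
#'
#' Inclusion is evaluated independently per target (the same shift records
#' are recoded for each), and an individual belongs to every cohort whose
#' own inclusion passes.  An individual with, e.g., 80% aggression days and
#' 20% self-injury days lands in AGG and SIB but not BOTH, whose imbalance
#' would exceed 90%.
#'
#' @param reports named list: for each individual id, a named list of
#'   [apply_inclusion()] reports keyed by target (`AGG`, `SIB`, `BOTH`).
#' @return data frame with one row per individual and logical columns
#'   `AGG`, `SIB`, `BOTH`.
#' @export
assign_cohorts <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  ids <- names(reports)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (tgt in c("AGG", "SIB", "BOTH")) {
    out[[tgt]] <- vapply(reports, function(r) {
      isTRUE(r[[tgt]]$passed)
    }, logical(1))
  }
  rownames(out) <- NULL
  out
}

#' Tabulate inclusion reports as a filter-cascade table
#'
#' One row per individual and target, one column per criterion, mirroring a
#' cohort-selection flow diagram.
#'
#' @param reports as in [assign_cohorts()].
#' @return data frame with columns `id`, `target`, `passed`, one logical
#'   column per criterion, `n_rows`, `majority_fraction`.
#' @export
inclusion_table <- function(reports) {
  criteria <- c("residency", "age", "asd_diagnosis", "min_points", "imbalance")
  rows <- list()
  for (id in names(reports)) {
    for (tgt in names(reports[[id]])) {
      r <- reports[[id]][[tgt]]
      row <- data.frame(id = id, target = tgt, passed = r$passed,
                        n_rows = r$n_rows, majority_fraction = r$majority_fraction)
      for (cr in criteria) row[[paste0("fail_", cr)]] <- cr %in% r$failed_criteria
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
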