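`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

## derive a sub-seed from a master seed; kept below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

#' Add calendar months to a date
#'
#' Same day-of-month in the target month, clamped to the last day of that
#' month (Jan 31 + 1 month = Feb 28/29), as a facility protocol would count
#' a "one-month" settling-in period.
#'
#' @param date a `Date`.
#' @param n number of months to add.
#' @return a `Date`.
#' @export
#' @examples
#' add_months(as.Date("2016-01-31"), 1)  # 2016-02-29
add_months <- function(date, n = 1L) {
  stopifnot(inherits(date, "Date"), length(date) == 1L)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  m2 <- m + as.integer(n)
  y2 <- y + (m2 - 1L) %/% 12L
  m2 <- ((m2 - 1L) %% 12L) + 1L
  ## last day of target month
  nm_y <- y2 + (m2 == 12L)
  nm_m <- (m2 %% 12L) + 1L
  last <- as.integer(format(as.Date(sprintf("%04d-%02d-01", nm_y, nm_m)) - 1L, "%d"))
  as.Date(sprintf("%04d-%02d-%02d", y2, m2, min(d, last)))
}

## parse "HH:MM:SS" to seconds since midnight
hms_to_seconds <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3L || anyNA(suppressWarnings(as.numeric(p)))) return(NA_real_)
    sum(as.numeric(p) * c(3600, 60, 1))
  }, numeric(1))
}

seconds_to_hms <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}
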