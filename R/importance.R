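## Excitation-based variable importance: one variable at a time is driven
## with standard-normal draws while all others are held at 0 (their
## standardized mean), and the spread of the network output measures that
## variable's influence.

#' Excite one input variable of a fitted model
#'
#' Builds `n_draws` input vectors whose component `k` is drawn from a
#' standard normal distribution while every other component is 0, and
#' returns the standard deviation of the model's probability outputs.
#' Because the model inputs are z-scored, the draws cover a range
#' comparable to the original standardized variable.
#'
#' @param model a `kernel_adaline` fit.
#' @param k variable index to excite.
#' @param n_draws number of standard-normal draws (default 1000).
#' @param seed RNG seed for the draws (kept independent of training seeds).
#' @return non-negative scalar: the standard deviation of the outputs.
#' @export
excite_variable <- function(model, k, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(model, "kernel_adaline"))
  p <- ncol(model$prototypes)
  stopifnot(k >= 1L, k <= p)
  set.seed(as.integer(seed))
  x <- matrix(0, nrow = n_draws, ncol = p)
  x[, k] <- stats::rnorm(n_draws)
  stats::sd(predict_proba(model, x))
}

#' Scale raw excitation spreads to the 0-8 importance convention
#'
#' Raw standard deviations are proportionally rescaled so that the largest
#' equals 8 (they are already bounded below by 0).  Tier thresholds follow
#' the Pareto-style convention: scaled scores above 2 mark significant
#' contributors, below 0.5 negligible ones, and 0.5-2 minor but noticeable
#' ones; scores above 4 are flagged for plotting under the stricter cutoff.
#'
#' @param raw named non-negative numeric vector of raw output standard
#'   deviations, one per variable.
#' @return data frame of class `importance_profile`: `variable`, `raw_sd`,
#'   `scaled` (in \[0, 8\]), `tier`, `plotted`.
#' @export
scale_importance <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1L, all(raw >= 0 | is.na(raw)))
  vars <- names(raw) %||% paste0("x", seq_along(raw))
  mx <- max(raw, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    warning("all raw excitation spreads are zero; all variables negligible",
            call. = FALSE)
    scaled <- rep(0, length(raw))
  } else {
    scaled <- 8 * raw / mx
  }
  tier <- ifelse(scaled > 2, "significant",
                 ifelse(scaled < 0.5, "negligible", "minor"))
  structure(data.frame(variable = vars, raw_sd = unname(raw),
                       scaled = unname(scaled), tier = tier,
                       plotted = scaled > 4),
            class = c("importance_profile", "data.frame"))
}

#' Excitation importance profile for every input variable
#'
#' Runs [excite_variable()] on each input of the fitted model (a dedicated
#' sub-seed per variable, derived from `seed`) and scales the results with
#' [scale_importance()].
#'
#' @param model a `kernel_adaline` fit.
#' @param n_draws draws per variable (default 1000).
#' @param seed master seed for the excitation draws.
#' @return an `importance_profile` data frame.
#' @export
variable_importance <- function(model, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(model, "kernel_adaline"))
  p <- ncol(model$prototypes)
  raw <- vapply(seq_len(p), function(k) {
    excite_variable(model, k, n_draws = n_draws, seed = derive_seed(seed, k))
  }, numeric(1))
  names(raw) <- model$var_names
  scale_importance(raw)
}

#' Summarize importance profiles across a cohort
#'
#' Counts, per variable, the individuals whose scaled importance exceeds 4
#' (the plotting cutoff) and 2 (the significance threshold).  The menses
#' variable is counted over female individuals only, and its denominator is
#' reported separately; with no females the menses counts are `NA`.
#'
#' @param profiles named list of `importance_profile` objects, one per
#'   individual id.
#' @param sex optional named character vector (`"F"`/`"M"`) per id; needed
#'   for the menses restriction.
#' @param menses_variable name of the menses variable (default `"menses"`).
#' @return data frame `variable`, `n_gt4`, `n_gt2`, `denominator`.
#' @export
summarize_importance <- function(profiles, sex = NULL,
                                 menses_variable = "menses") {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  ids <- names(profiles) %||% as.character(seq_along(profiles))
  vars <- unique(unlist(lapply(profiles, function(p) p$variable)))
  female_ids <- if (is.null(sex)) character() else names(sex)[sex == "F"]
  out <- lapply(vars, function(v) {
    use <- if (v == menses_variable && !is.null(sex)) {
      ids[ids %in% female_ids]
    } else ids
    if (length(use) == 0L) {
      return(data.frame(variable = v, n_gt4 = NA_integer_,
                        n_gt2 = NA_integer_, denominator = 0L))
    }
    sc <- vapply(use, function(id) {
      p <- profiles[[id]]
      s <- p$scaled[p$variable == v]
      if (length(s) == 1L) s else NA_real_
    }, numeric(1))
    data.frame(variable = v, n_gt4 = sum(sc > 4, na.rm = TRUE),
               n_gt2 = sum(sc > 2, na.rm = TRUE),
               denominator = sum(!is.na(sc)))
  })
  do.call(rbind, out)
}
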