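## Shared fixtures, built in code at test time.

## one synthetic individual run through cleaning/features/standardization,
## returning the model-ready matrix and labels
make_modeled_individual <- function(mechanism = "logistic_additive",
                                    weights = c(constipation = 2,
                                                sleep_hours = -1.5),
                                    base_rate = 0.3, days = 400, seed = 1,
                                    target = "BOTH", ...) {
  cfg <- synth_config(n_individuals = 1, days_per_individual = days,
                      behavior_mechanism = mechanism,
                      effect_weights = weights, base_rate = base_rate,
                      seed = seed, ...)
  ind <- generate_cohort(cfg)$individuals[[1]]
  daily <- engineer_gi(build_daily_records(ind))
  labels <- code_behavior_days(ind$behavior, target)
  rows <- align_days(daily, labels)
  std <- standardize_rows(rows)
  list(x = as.matrix(std$rows[, std$params$variable, drop = FALSE]),
       y = std$rows$y, rows = rows, std = std, ind = ind, daily = daily)
}

## shift-table builder: statuses is a list of length-3 character vectors,
## categories a list of length-3 category strings
make_shift_table <- function(statuses, categories = NULL,
                             start = as.Date("2020-01-01")) {
  n <- length(statuses)
  if (is.null(categories)) categories <- rep(list(c("", "", "")), n)
  data.frame(
    date = rep(start + seq_len(n) - 1L, each = 3L),
    shift = rep(c("07-15", "15-23", "23-07"), times = n),
    status = unlist(statuses),
    category = unlist(categories),
    stringsAsFactors = FALSE
  )
}

## BM event-table row builder
bm_row <- function(date, record_type = "event", reporter = "staff",
                   bristol = NA_real_, size = "", note = FALSE) {
  data.frame(date = as.Date(date), record_type = record_type,
             reporter = reporter, bristol = bristol, size = size,
             note = note, stringsAsFactors = FALSE)
}

## independent brute-force oracle for the kernel transform: elementwise
## arithmetic, no matrix algebra shared with the implementation
brute_force_kernel <- function(x, prototypes, sigma) {
  out <- matrix(NA_real_, nrow(x), nrow(prototypes))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(prototypes))) {
      d2 <- 0
      for (k in seq_len(ncol(x))) d2 <- d2 + (x[i, k] - prototypes[j, k])^2
      out[i, j] <- exp(-d2 / sigma)
    }
  }
  out
}

## two linearly separable Gaussian blobs
make_blobs <- function(n = 100, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n), n / 2, 2), matrix(rnorm(n) + gap, n / 2, 2))
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}

## hand-built kernel_adaline object (for tests that need exact weights)
manual_model <- function(prototypes, weights, bias, sigma = 1,
                         var_names = NULL) {
  structure(list(prototypes = as.matrix(prototypes), sigma = sigma,
                 weights = weights, bias = bias, epochs = 0L,
                 learning_rate = 0, update_rule = "logistic", loss = 0,
                 var_names = var_names %||%
                   paste0("x", seq_len(ncol(as.matrix(prototypes))))),
            class = "kernel_adaline")
}

## minimal split_eval stand-in for report-level tests
fake_eval <- function(mean_bcr, majority_fraction = 0.7,
                      mean_sensitivity = mean_bcr,
                      mean_specificity = mean_bcr) {
  structure(list(splits = NULL, median_bcr = mean_bcr, mean_bcr = mean_bcr,
                 mean_sensitivity = mean_sensitivity,
                 mean_specificity = mean_specificity, n_valid = 30L,
                 majority_fraction = majority_fraction, evaluable = TRUE,
                 method = "kernel"),
            class = "split_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
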