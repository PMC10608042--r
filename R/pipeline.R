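## End-to-end orchestration: synth -> clean -> features -> cohort -> model
## -> importance -> report, with a manifest and a plain-text run log.

#' Validate a full pipeline configuration
#'
#' Every stage's settings are validated here, before any stage runs.
#'
#' @param cohorts behavior targets to analyze (subset of `"AGG"`, `"SIB"`,
#'   `"BOTH"`).
#' @param synth a [synth_config()] describing the cohort to generate, or
#'   `NULL` to read data from `data_dir`.
#' @param data_dir directory of per-individual source CSVs (see
#'   [read_cohort()]); required when `synth` is `NULL`.
#' @param n_splits,train_fraction evaluation protocol settings.
#' @param n_prototypes,epochs,learning_rate,sigma,threshold kernel model
#'   settings ([fit_kernel_adaline()], [evaluate_splits()]).
#' @param clinical_threshold BCR threshold for the report stage.
#' @param max_months data horizon per individual in months (default 18).
#' @param seed master seed for model/importance randomness.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts = c("AGG", "SIB", "BOTH"),
                            synth = NULL, data_dir = NULL,
                            n_splits = 30L, train_fraction = 0.85,
                            n_prototypes = 15L, epochs = 1000L,
                            learning_rate = 0.01, sigma = NULL,
                            threshold = 0.5, clinical_threshold = 0.80,
                            max_months = 18L, seed = 1L) {
  bad <- setdiff(cohorts, c("AGG", "SIB", "BOTH"))
  if (length(bad) > 0L) {
    stop("unknown cohort name(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(synth) && is.null(data_dir)) {
    stop("either a synth config or a data_dir must be given")
  }
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  stopifnot(n_splits >= 1L, train_fraction > 0, train_fraction < 1,
            n_prototypes >= 1L, epochs >= 1L, learning_rate > 0,
            threshold > 0, threshold < 1, max_months >= 1L)
  structure(list(cohorts = cohorts, synth = synth, data_dir = data_dir,
                 n_splits = as.integer(n_splits),
                 train_fraction = train_fraction,
                 n_prototypes = as.integer(n_prototypes),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 sigma = sigma, threshold = threshold,
                 clinical_threshold = clinical_threshold,
                 max_months = as.integer(max_months), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage against a synthetic or on-disk cohort and writes
#' all artifacts to `out_dir`: the (possibly generated) source data, the
#' inclusion cascade table, per-individual model results for the kernel and
#' linear classifiers, importance profiles with a cohort summary, the
#' BCR-vs-imbalance table, the variable dendrogram in Newick form, a run
#' log recording every dropped day/row/individual, and a manifest with an
#' MD5 checksum per artifact.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the manifest data frame and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run-log.txt")
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  manifest <- list()
  record <- function(files, stage) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(file = files, stage = stage,
                 md5 = unname(tools::md5sum(files)))
  }

  ## --- stage 1: data
  if (!is.null(config$synth)) {
    cohort <- inject_missingness(generate_cohort(config$synth), config$synth)
    data_dir <- file.path(out_dir, "data")
    files <- write_cohort(cohort, data_dir)
    record(files, "synth")
    note("synth: generated %d individuals (seed %d)",
         length(cohort$individuals), config$synth$seed)
  } else {
    cohort <- read_cohort(config$data_dir)
    note("data: read %d individuals from %s", length(cohort$individuals),
         config$data_dir)
  }

  ## --- stages 2-3: clean + features per individual and target
  rows_by_target <- setNames(vector("list", length(config$cohorts)), config$cohorts)
  meta_by_id <- list()
  for (id in names(cohort$individuals)) {
    ind <- cohort$individuals[[id]]
    daily <- engineer_gi(build_daily_records(ind))
    meta <- ind$meta
    start <- determine_start(meta$admission,
                             min(as.Date(ind$behavior$date)),
                             min(as.Date(ind$sleep$date)),
                             min(as.Date(ind$bm$date)))
    horizon <- add_months(start, config$max_months)
    meta$start <- start
    meta_by_id[[id]] <- meta
    for (tgt in config$cohorts) {
      labels <- suppressWarnings(code_behavior_days(ind$behavior, tgt))
      rows <- align_days(daily, labels)
      kept <- rows$date >= start & rows$date < horizon
      note("features[%s,%s]: %d candidate, %d dropped missing, %d in window",
           id, tgt, attr(rows, "n_candidate"), attr(rows, "n_dropped_missing"),
           sum(kept))
      rows <- rows[kept, , drop = FALSE]
      rows$individual <- id
      rows_by_target[[tgt]] <- c(rows_by_target[[tgt]], setNames(list(rows), id))
    }
  }

  results_all <- list()
  importance_all <- list()
  sex_by_id <- vapply(meta_by_id, function(m) m$sex %||% NA_character_,
                      character(1))
  for (tgt in config$cohorts) {
    std <- standardize_rows(rows_by_target[[tgt]])
    if (length(std$dropped) > 0L) {
      note("standardize[%s]: dropped zero-variance variable(s) %s", tgt,
           paste(std$dropped, collapse = ", "))
    }
    ## --- stage 4: inclusion
    reports <- list()
    for (id in names(std$rows)) {
      reports[[id]] <- apply_inclusion(
        c(meta_by_id[[id]], list(age_at_start = meta_by_id[[id]]$age_at_start)),
        std$rows[[id]])
      if (!reports[[id]]$passed) {
        note("inclusion[%s,%s]: excluded (%s)", id, tgt,
             paste(reports[[id]]$failed_criteria, collapse = ", "))
      }
    }
    inc_tab <- inclusion_table(setNames(lapply(names(reports), function(id) {
      setNames(list(reports[[id]]), tgt)
    }), names(reports)))
    f <- file.path(out_dir, sprintf("inclusion-%s.csv", tgt))
    utils::write.csv(inc_tab, f, row.names = FALSE)
    record(f, "cohort")

    included <- names(reports)[vapply(reports, function(r) r$passed, logical(1))]

    ## --- stage 5: models
    res_kernel <- list(); res_linear <- list()
    for (id in included) {
      r <- std$rows[[id]]
      x <- as.matrix(r[, std$params$variable, drop = FALSE])
      for (m in c("kernel", "linear")) {
        ev <- evaluate_splits(x, r$y, n_splits = config$n_splits,
                              train_fraction = config$train_fraction,
                              method = m, n_prototypes = config$n_prototypes,
                              epochs = config$epochs,
                              learning_rate = config$learning_rate,
                              sigma = config$sigma,
                              threshold = config$threshold)
        if (m == "kernel") res_kernel[[id]] <- ev else res_linear[[id]] <- ev
      }
    }
    if (length(included) == 0L) {
      note("model[%s]: no individuals pass inclusion; cohort skipped", tgt)
      results_all[[tgt]] <- list(kernel = list(), linear = list(),
                                 inclusion = reports, table = NULL,
                                 threshold_summary = NULL, imbalance = NULL,
                                 clustering = NULL)
      importance_all[[tgt]] <- list()
      next
    }
    res_df <- do.call(rbind, lapply(included, function(id) {
      data.frame(id = id, cohort = tgt,
                 n_rows = nrow(std$rows[[id]]),
                 majority_fraction = res_kernel[[id]]$majority_fraction,
                 kernel_mean_bcr = res_kernel[[id]]$mean_bcr,
                 kernel_median_bcr = res_kernel[[id]]$median_bcr,
                 kernel_mean_sensitivity = res_kernel[[id]]$mean_sensitivity,
                 kernel_mean_specificity = res_kernel[[id]]$mean_specificity,
                 n_valid_splits = res_kernel[[id]]$n_valid,
                 linear_mean_bcr = res_linear[[id]]$mean_bcr)
    }))
    f <- file.path(out_dir, sprintf("results-%s.csv", tgt))
    utils::write.csv(res_df, f, row.names = FALSE)
    record(f, "model")

    ## --- stage 6: importance (full-data fit per individual)
    profiles <- list()
    for (id in included) {
      r <- std$rows[[id]]
      x <- as.matrix(r[, std$params$variable, drop = FALSE])
      if (length(unique(r$y)) < 2L) next
      fit <- fit_kernel_adaline(x, r$y, n_prototypes = config$n_prototypes,
                                epochs = config$epochs,
                                learning_rate = config$learning_rate,
                                sigma = config$sigma,
                                seed = derive_seed(config$seed, 9000L))
      profiles[[id]] <- variable_importance(fit,
                                            seed = derive_seed(config$seed, 9100L))
    }
    if (length(profiles) > 0L) {
      imp_df <- do.call(rbind, lapply(names(profiles), function(id) {
        cbind(id = id, as.data.frame(profiles[[id]]))
      }))
      f <- file.path(out_dir, sprintf("importance-%s.csv", tgt))
      utils::write.csv(imp_df, f, row.names = FALSE)
      record(f, "importance")
      summ <- summarize_importance(profiles, sex = sex_by_id[names(profiles)])
      f <- file.path(out_dir, sprintf("importance-summary-%s.csv", tgt))
      utils::write.csv(summ, f, row.names = FALSE)
      record(f, "importance")
    }

    ## --- stage 7: report
    thr <- threshold_summary(res_kernel, threshold = config$clinical_threshold)
    imb <- bcr_vs_imbalance(res_kernel)
    f <- file.path(out_dir, sprintf("bcr-vs-imbalance-%s.csv", tgt))
    utils::write.csv(imb$table, f, row.names = FALSE)
    record(f, "report")
    note("report[%s]: %d/%d individuals above BCR %.2f; spearman rho %.3f",
         tgt, thr$n_above, thr$n, config$clinical_threshold,
         imb$spearman_rho %||% NA_real_)
    if (length(thr$ids_above) >= 2L) {
      cl <- cluster_variables(std$rows[thr$ids_above])
      f <- file.path(out_dir, sprintf("variable-clusters-%s.nwk", tgt))
      writeLines(cl$newick, f)
      record(f, "report")
    } else {
      note("report[%s]: < 2 individuals above threshold; clustering skipped", tgt)
      cl <- NULL
    }
    results_all[[tgt]] <- list(kernel = res_kernel, linear = res_linear,
                               inclusion = reports, table = res_df,
                               threshold_summary = thr, imbalance = imb,
                               clustering = cl)
    importance_all[[tgt]] <- profiles
  }

  writeLines(log_lines, log_path)
  manifest_df <- do.call(rbind, manifest)
  manifest_df <- rbind(manifest_df,
                       data.frame(file = log_path, stage = "log",
                                  md5 = unname(tools::md5sum(log_path))))
  mf <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest_df, mf, row.names = FALSE)
  invisible(list(manifest = manifest_df, results = results_all,
                 importance = importance_all))
}
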