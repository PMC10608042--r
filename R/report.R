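## Downstream summaries: clinical-threshold counts, the BCR-vs-imbalance
## relationship, and correlation clustering of the model variables.

#' Count individuals above a clinical BCR threshold
#'
#' A balanced accuracy above 80% is the conventional minimum for acting on
#' predictions in practice; this tabulates how many evaluated individuals
#' per cohort clear a threshold.
#'
#' @param results named list of `split_eval` objects keyed by individual id.
#' @param threshold BCR threshold (default 0.80).
#' @param stat aggregate to compare: `"mean_bcr"` (default) or
#'   `"median_bcr"`.
#' @return list: `n` evaluable individuals, `n_above`, `fraction`,
#'   `ids_above`.
#' @export
threshold_summary <- function(results, threshold = 0.80, stat = "mean_bcr") {
  stopifnot(is.list(results), stat %in% c("mean_bcr", "median_bcr"))
  ids <- names(results) %||% as.character(seq_along(results))
  vals <- vapply(results, function(r) r[[stat]], numeric(1))
  ok <- !is.na(vals)
  list(n = sum(ok),
       n_above = sum(vals[ok] > threshold),
       fraction = if (any(ok)) sum(vals[ok] > threshold) / sum(ok) else NA_real_,
       ids_above = ids[ok][vals[ok] > threshold])
}

#' Relate per-individual performance to class imbalance
#'
#' Emits one row per individual (majority fraction, mean sensitivity,
#' specificity, BCR) and the Spearman rank correlation between the majority
#' fraction and mean BCR.  Individuals with less class imbalance tend to be
#' predicted better; the correlation quantifies that trend.
#'
#' @param results named list of `split_eval` objects.
#' @return list with `table` (data frame) and `spearman_rho` (NA when the
#'   correlation is undefined, e.g. zero variance).
#' @export
bcr_vs_imbalance <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  ids <- names(results) %||% as.character(seq_along(results))
  tab <- data.frame(
    id = ids,
    majority_fraction = vapply(results, function(r) r$majority_fraction, numeric(1)),
    mean_sensitivity = vapply(results, function(r) r$mean_sensitivity, numeric(1)),
    mean_specificity = vapply(results, function(r) r$mean_specificity, numeric(1)),
    mean_bcr = vapply(results, function(r) r$mean_bcr, numeric(1))
  )
  rownames(tab) <- NULL
  ok <- stats::complete.cases(tab[, c("majority_fraction", "mean_bcr")])
  rho <- if (sum(ok) >= 3L &&
             stats::sd(tab$majority_fraction[ok]) > 0 &&
             stats::sd(tab$mean_bcr[ok]) > 0) {
    suppressWarnings(stats::cor(tab$majority_fraction[ok], tab$mean_bcr[ok],
                                method = "spearman"))
  } else NA_real_
  list(table = tab, spearman_rho = rho)
}

#' Hierarchically cluster model variables by correlation
#'
#' Pools the standardized feature rows of the qualifying individuals
#' (typically those whose BCR exceeds 80%), computes the distance
#' `1 - |Pearson correlation|` between variables (sign is irrelevant to
#' redundancy), and applies average-linkage agglomerative clustering.  The
#' dendrogram is also serialized to Newick.
#'
#' @param rows a data frame (or list of data frames, pooled by row-binding)
#'   of standardized feature rows; non-predictor columns `date`, `y`,
#'   `individual` are ignored.
#' @param k number of clusters to cut (default 3).
#' @return object of class `variable_clustering`: `variables`, `distance`
#'   (matrix), `hclust`, `clusters` (cut at `k`), `k`, `newick`.
#' @export
cluster_variables <- function(rows, k = 3L) {
  if (is.data.frame(rows)) rows <- list(rows)
  stopifnot(length(rows) >= 1L)
  pooled <- do.call(rbind, rows)
  pooled <- pooled[, setdiff(names(pooled), c("date", "y", "individual")),
                   drop = FALSE]
  if (ncol(pooled) < 3L) stop("variable clustering needs at least 3 variables")
  cm <- suppressWarnings(stats::cor(as.matrix(pooled)))
  cm[is.na(cm)] <- 0  # zero-variance guard; treated as uncorrelated
  d <- 1 - abs(cm)
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  k <- min(as.integer(k), ncol(pooled))
  structure(list(variables = colnames(pooled), distance = d, hclust = hc,
                 clusters = stats::cutree(hc, k = k), k = k,
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "variable_clustering")
}

#' @export
print.variable_clustering <- function(x, ...) {
  cat(sprintf("Correlation clustering of %d variables (cut at k = %d)\n",
              length(x$variables), x$k))
  for (cl in sort(unique(x$clusters))) {
    cat(sprintf("  cluster %d: %s\n", cl,
                paste(names(x$clusters)[x$clusters == cl], collapse = ", ")))
  }
  invisible(x)
}
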