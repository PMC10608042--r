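## Direct-kernel ADALINE classifier and the repeated-random-split BCR
## evaluation protocol, plus the linear logistic-regression benchmark.

#' Direct kernel transformation
#'
#' Maps each input vector to similarity features against a fixed set of
#' prototype vectors: `f_ij = exp(-||x_i - p_j||^2 / sigma)`.  Every feature
#' lies in (0, 1], reaching 1 exactly when the input coincides with the
#' prototype.
#'
#' @param x numeric matrix of inputs (rows) or a single numeric vector.
#' @param prototypes numeric matrix of prototype rows with the same number
#'   of columns as `x`.
#' @param sigma positive kernel scaling parameter.
#' @return matrix of kernel features, one column per prototype.
#' @export
kernel_features <- function(x, prototypes, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  prototypes <- as.matrix(prototypes)
  if (ncol(x) != ncol(prototypes)) {
    stop("input dimension ", ncol(x), " does not match prototype dimension ",
         ncol(prototypes))
  }
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  d2 <- outer(rowSums(x^2), rowSums(prototypes^2), "+") -
    2 * (x %*% t(prototypes))
  d2 <- pmax(d2, 0)  # guard tiny negative round-off
  exp(-d2 / sigma)
}

#' Median-heuristic kernel parameter
#'
#' The median of the pairwise squared Euclidean distances among the
#' training rows; falls back to 1 when fewer than two distinct rows exist.
#'
#' @param x numeric matrix of training rows.
#' @return positive scalar.
#' @export
median_sigma <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) return(1)
  m <- stats::median(stats::dist(x)^2)
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Fit a direct-kernel ADALINE classifier
#'
#' Prototypes are drawn uniformly without replacement from the training
#' rows; inputs are kernel-transformed against them; and a single-layer
#' unit (weights + bias) is trained on the features by the sequential
#' Widrow-Hoff rule with targets in {0, 1}, reshuffling the presentation
#' order each epoch.  By default the per-sample error is taken on the
#' logistic-activated output (`update_rule = "logistic"`), so the network
#' output is a calibrated probability and the 0.5 classification threshold
#' is meaningful.  `update_rule = "linear"` applies the literal LMS update
#' to the pre-activation instead; its regression output for {0, 1} targets
#' concentrates in \[0, 1\], which drives `plogis(output)` above 0.5 almost
#' everywhere and degenerates the thresholded classifier, so it is kept
#' only as the textbook reference form.
#'
#' @param x numeric matrix of standardized predictors.
#' @param y binary response vector (0/1), both classes present.
#' @param n_prototypes number of prototypes (default 15).
#' @param epochs training epochs (default 1000).
#' @param learning_rate LMS step size (default 0.01).
#' @param sigma kernel parameter; `NULL` (default) uses [median_sigma()] of
#'   the training rows.
#' @param update_rule `"logistic"` (default) or `"linear"`, see Details.
#' @param seed integer seed controlling prototype sampling and epoch
#'   shuffling.
#' @return object of class `kernel_adaline` with elements `prototypes`,
#'   `sigma`, `weights`, `bias`, `loss` (per-epoch mean squared error),
#'   `var_names`.
#' @export
fit_kernel_adaline <- function(x, y, n_prototypes = 15L, epochs = 1000L,
                               learning_rate = 0.01, sigma = NULL,
                               update_rule = c("logistic", "linear"),
                               seed = 1L) {
  update_rule <- match.arg(update_rule)
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("training set contains a single class; cannot fit")
  }
  n <- nrow(x)
  if (n < n_prototypes) {
    warning("fewer training rows (", n, ") than prototypes (", n_prototypes,
            "); using ", n, call. = FALSE)
    n_prototypes <- n
  }
  set.seed(as.integer(seed))
  proto_idx <- sample.int(n, n_prototypes)
  prototypes <- x[proto_idx, , drop = FALSE]
  sigma <- sigma %||% median_sigma(x)
  f <- kernel_features(x, prototypes, sigma)
  order_mat <- vapply(seq_len(epochs), function(e) sample.int(n), integer(n))
  fit <- lms_train(f, y, learning_rate, order_mat,
                   logistic_update = update_rule == "logistic")
  structure(list(prototypes = prototypes, sigma = sigma,
                 weights = as.numeric(fit$weights), bias = as.numeric(fit$bias),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 update_rule = update_rule,
                 loss = as.numeric(fit$loss),
                 var_names = colnames(x) %||% paste0("x", seq_len(ncol(x)))),
            class = "kernel_adaline")
}

#' @export
print.kernel_adaline <- function(x, ...) {
  cat("Direct-kernel ADALINE classifier\n")
  cat(sprintf("  %d prototypes in %d dimensions, sigma = %.4g\n",
              nrow(x$prototypes), ncol(x$prototypes), x$sigma))
  cat(sprintf("  trained %d epochs (eta = %g); final MSE %.4f\n",
              x$epochs, x$learning_rate, x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict behavior probability from a fitted kernel ADALINE
#'
#' The linear combination of the kernel features plus the bias is passed
#' through the logistic activation, yielding the probability that the
#' individual exhibits the target behavior the next day.
#'
#' @param model a `kernel_adaline` fit.
#' @param x matrix (or vector) of predictors on the model's input scale.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "kernel_adaline"))
  f <- kernel_features(x, model$prototypes, model$sigma)
  as.numeric(stats::plogis(f %*% model$weights + model$bias))
}

#' @export
predict.kernel_adaline <- function(object, newdata,
                                   type = c("prob", "class"),
                                   threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p > threshold)
}

#' Sensitivity, specificity, and balanced classification rate
#'
#' BCR = (sensitivity + specificity) / 2, the metric of choice under class
#' imbalance: a majority-class classifier scores 0.5 regardless of how
#' lopsided the classes are.
#'
#' @param y true binary labels.
#' @param pred predicted binary labels.
#' @return named list `sensitivity`, `specificity`, `bcr` (NA when a class
#'   is absent from `y`).
#' @export
classification_rates <- function(y, pred) {
  y <- as.integer(y); pred <- as.integer(pred)
  sens <- if (sum(y == 1L) > 0L) mean(pred[y == 1L] == 1L) else NA_real_
  spec <- if (sum(y == 0L) > 0L) mean(pred[y == 0L] == 0L) else NA_real_
  list(sensitivity = sens, specificity = spec, bcr = (sens + spec) / 2)
}

fit_linear_ridge <- function(x, y, lambda = 1e-6) {
  ## ridge-penalized logistic regression; the tiny penalty guarantees a
  ## finite solution under complete separation
  x <- as.matrix(x)
  if (ncol(x) == 1L) x <- cbind(x, `.zero` = 0)  # glmnet needs >= 2 columns
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                 standardize = FALSE)
}

predict_linear_ridge <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) == 1L) x <- cbind(x, `.zero` = 0)
  as.numeric(predict(fit, newx = x, type = "response"))
}

#' Evaluate a per-individual classifier over repeated random splits
#'
#' For each of `n_splits` seeded random splits into 85% training and 15%
#' validation data, fits the chosen classifier on the training portion and
#' scores sensitivity, specificity, and BCR on the validation portion at
#' the probability threshold.  Splits whose validation (or training) set
#' lacks one of the two classes are marked invalid and excluded from the
#' aggregates.  Split seeds default to the integers 1..n_splits.
#'
#' @param x standardized predictor matrix for one individual.
#' @param y binary next-day behavior labels.
#' @param n_splits number of random splits (default 30).
#' @param train_fraction training share of rows (default 0.85).
#' @param method `"kernel"` (direct-kernel ADALINE) or `"linear"`
#'   (ridge-stabilized logistic regression on the original variables).
#' @param n_prototypes,epochs,learning_rate,sigma kernel model settings,
#'   see [fit_kernel_adaline()].
#' @param threshold classification probability threshold (default 0.5).
#' @param seed_base offset added to the split index to form each split's
#'   seed (default 0, i.e. seeds 1..n_splits).
#' @return object of class `split_eval`: data frame `splits` (`seed`,
#'   `sensitivity`, `specificity`, `bcr`, `valid`), aggregates
#'   `median_bcr`, `mean_bcr`, `mean_sensitivity`, `mean_specificity` over
#'   valid splits, `n_valid`, `majority_fraction`, `evaluable`, `method`.
#' @export
evaluate_splits <- function(x, y, n_splits = 30L, train_fraction = 0.85,
                            method = c("kernel", "linear"),
                            n_prototypes = 15L, epochs = 1000L,
                            learning_rate = 0.01, sigma = NULL,
                            threshold = 0.5, seed_base = 0L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  stopifnot(n == length(y), n >= 4L)
  res <- data.frame(seed = integer(n_splits), sensitivity = NA_real_,
                    specificity = NA_real_, bcr = NA_real_, valid = FALSE)
  for (s in seq_len(n_splits)) {
    sp_seed <- as.integer(seed_base) + s
    res$seed[s] <- sp_seed
    set.seed(sp_seed)
    tr <- sample.int(n, round(train_fraction * n))
    va <- setdiff(seq_len(n), tr)
    if (length(unique(y[va])) < 2L || length(unique(y[tr])) < 2L) next
    p <- if (method == "kernel") {
      fit <- fit_kernel_adaline(x[tr, , drop = FALSE], y[tr],
                                n_prototypes = n_prototypes, epochs = epochs,
                                learning_rate = learning_rate, sigma = sigma,
                                seed = sp_seed)
      predict_proba(fit, x[va, , drop = FALSE])
    } else {
      fit <- fit_linear_ridge(x[tr, , drop = FALSE], y[tr])
      predict_linear_ridge(fit, x[va, , drop = FALSE])
    }
    rates <- classification_rates(y[va], as.integer(p > threshold))
    res$sensitivity[s] <- rates$sensitivity
    res$specificity[s] <- rates$specificity
    res$bcr[s] <- rates$bcr
    res$valid[s] <- TRUE
  }
  ok <- res$valid
  structure(list(
    splits = res,
    median_bcr = if (any(ok)) stats::median(res$bcr[ok]) else NA_real_,
    mean_bcr = if (any(ok)) mean(res$bcr[ok]) else NA_real_,
    mean_sensitivity = if (any(ok)) mean(res$sensitivity[ok]) else NA_real_,
    mean_specificity = if (any(ok)) mean(res$specificity[ok]) else NA_real_,
    n_valid = sum(ok),
    majority_fraction = max(mean(y), 1 - mean(y)),
    evaluable = any(ok),
    method = method
  ), class = "split_eval")
}

#' @export
print.split_eval <- function(x, ...) {
  cat(sprintf("%s model: %d/%d valid splits\n",
              x$method, x$n_valid, nrow(x$splits)))
  cat(sprintf("  mean BCR %.3f (median %.3f); sens %.3f, spec %.3f; majority %.2f\n",
              x$mean_bcr, x$median_bcr, x$mean_sensitivity,
              x$mean_specificity, x$majority_fraction))
  invisible(x)
}
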