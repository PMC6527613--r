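#' Classification evaluation report
#'
#' Agreement, sensitivity and specificity (all in percent) against expert
#' labels, with `abnormal` as the positive class:
#' agreement = (TP+TN)/(TP+TN+FP+FN) * 100, sensitivity = TP/(TP+FN) * 100,
#' specificity = TN/(TN+FP) * 100.
#'
#' @param preds,labels Equal-length label vectors, either binary (1 =
#'   abnormal) or character `normal`/`abnormal`.
#' @return An object of class `eval_report` with the confusion counts and
#'   the three percentage metrics.
#' @export
evaluate <- function(preds, labels) {
  if (length(preds) == 0L || length(preds) != length(labels)) {
    stop("preds and labels must be nonempty and of equal length",
      call. = FALSE
    )
  }
  p <- label_to_binary(preds)
  y <- label_to_binary(labels)
  eval_report(
    tp = sum(p == 1L & y == 1L), tn = sum(p == 0L & y == 0L),
    fp = sum(p == 1L & y == 0L), fn = sum(p == 0L & y == 1L)
  )
}

eval_report <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  structure(
    list(
      tp = tp, tn = tn, fp = fp, fn = fn, n = n,
      agreement = 100 * (tp + tn) / n,
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "eval_report (n = %d): agreement %.1f%%, sensitivity %.1f%%, ",
      "specificity %.1f%% [TP %d TN %d FP %d FN %d]\n"
    ),
    x$n, x$agreement, x$sensitivity, x$specificity, x$tp, x$tn, x$fp, x$fn
  ))
  invisible(x)
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement. When the expected agreement is 1
#' (both raters constant on the same class) kappa is undefined and `NA` is
#' returned with a warning.
#'
#' @param labels_a,labels_b Equal-length binary or normal/abnormal vectors.
#' @return Kappa in [-1, 1], or `NA` when undefined.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) == 0L || length(labels_a) != length(labels_b)) {
    stop("label vectors must be nonempty and of equal length", call. = FALSE)
  }
  a <- label_to_binary(labels_a)
  b <- label_to_binary(labels_b)
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a == 1L) * mean(b == 1L) + mean(a == 0L) * mean(b == 0L)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("Cohen's kappa is undefined: expected agreement equals 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Stratified 4-fold cross-validation
#'
#' Splits the dataset into 4 label-stratified folds (per-class fold sizes
#' differ by at most one); each fold is evaluated with a model trained from
#' scratch on the remaining three. The averaged report pools the confusion
#' counts of all folds, so its agreement equals the sample-weighted mean of
#' the fold agreements.
#'
#' @param dataset List of labeled [polar_map] objects (one condition) or a
#'   list with `X` and `y`.
#' @param model_cfg A [model_config].
#' @param train_cfg A [train_config].
#' @param seed Seed for the fold assignment shuffle.
#' @param hierarchy Optional shared [coarsen] hierarchy for graph models.
#' @param return_models Keep the per-fold trained models (and fold index
#'   vectors) in the result.
#' @return List with `folds` (per-fold `eval_report`s), `mean` (pooled
#'   report), `fold_of` (fold id per sample) and optionally `models`.
#' @export
crossval_4fold <- function(dataset, model_cfg, train_cfg = train_config(),
                           seed = 0L, hierarchy = NULL,
                           return_models = FALSE) {
  ds <- as_dataset(dataset)
  n <- nrow(ds$X)
  k <- 4L
  if (n < 2L * k) stop("need at least 8 samples for 4-fold CV", call. = FALSE)
  fold_of <- integer(n)
  .with_seed(seed, {
    for (cls in unique(ds$y)) {
      idx <- which(ds$y == cls)
      fold_of[idx[sample.int(length(idx))]] <- rep_len(1:k, length(idx))
    }
  })
  needs_hier <- model_cfg$kind %in% c("gcnn_cheb", "gcnn_cayley")
  if (needs_hier && is.null(hierarchy)) {
    hierarchy <- coarsen(build_polar_adjacency(polar_grid()), n_levels = 3L)
  }
  folds <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_of != f
    te <- !tr
    model <- build_model(model_cfg, hierarchy = if (needs_hier) hierarchy)
    model <- train(model, list(X = ds$X[tr, , drop = FALSE], y = ds$y[tr]),
      cfg = train_cfg
    )
    preds <- predict(model, ds$X[te, , drop = FALSE], type = "class")
    folds[[f]] <- evaluate(preds, ds$y[te])
    if (return_models) models[[f]] <- model
  }
  pooled <- eval_report(
    tp = sum(vapply(folds, `[[`, numeric(1), "tp")),
    tn = sum(vapply(folds, `[[`, numeric(1), "tn")),
    fp = sum(vapply(folds, `[[`, numeric(1), "fp")),
    fn = sum(vapply(folds, `[[`, numeric(1), "fn"))
  )
  out <- list(folds = folds, mean = pooled, fold_of = fold_of)
  if (return_models) out$models <- models
  out
}
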