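#' Confusion counts and derived classification metrics
#'
#' Counts true/false positives and negatives against the designated
#' positive (disease) class and derives precision, recall (= sensitivity),
#' specificity and the F-measure (harmonic mean of precision and recall).
#' Metrics with a zero denominator are defined as 0.
#'
#' @param y_true,y_pred Equal-length class vectors; every value must be one
#'   of the two known labels.
#' @param positive_class The label counted as positive.
#' @return An object of class `metrics_report` with fields `tp`, `fp`,
#'   `tn`, `fn`, `precision`, `recall`, `f_measure`, `sensitivity`,
#'   `specificity`, `n`, `positive_class`.
#' @examples
#' confusion_metrics(rep(c("d", "h"), c(5, 5)),
#'                   rep(c("d", "h", "d", "h"), c(4, 1, 1, 4)), "d")
#' @export
confusion_metrics <- function(y_true, y_pred, positive_class) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) == 0L)
    stop("'y_true' and 'y_pred' must be non-empty and of equal length")
  known <- union(unique(y_true), positive_class)
  if (!all(y_pred %in% known))
    stop("unknown predicted label: ",
         paste(setdiff(y_pred, known), collapse = ", "))
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  tp <- sum(pos_t & pos_p); fp <- sum(!pos_t & pos_p)
  fn <- sum(pos_t & !pos_p); tn <- sum(!pos_t & !pos_p)
  div <- function(a, b) if (b > 0) a / b else 0
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall,
                 f_measure = div(2 * precision * recall, precision + recall),
                 sensitivity = recall,
                 specificity = div(tn, tn + fp),
                 n = length(y_true), positive_class = positive_class),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d (positive: %s)\n", x$n, x$positive_class))
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  F=%.3f precision=%.3f recall=%.3f sensitivity=%.3f specificity=%.3f\n",
              x$f_measure, x$precision, x$recall, x$sensitivity,
              x$specificity))
  invisible(x)
}

as_metrics_row <- function(x)
  data.frame(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
             precision = x$precision, recall = x$recall,
             f_measure = x$f_measure, sensitivity = x$sensitivity,
             specificity = x$specificity)

#' Stratified fold assignment
#'
#' Partitions subjects into `k` non-overlapping folds of quasi-equal class
#' distribution: every subject appears in exactly one fold, fold sizes
#' differ by at most 1, and each fold's per-class counts are within 1 of
#' proportionality. Per class, subjects are shuffled by `seed` and dealt
#' `floor(n_class / k)` to every fold, with the remainders going to the
#' currently smallest folds.
#'
#' @param labels Class vector.
#' @param k Number of folds; must not exceed the smaller class count.
#' @param seed Integer RNG seed.
#' @return An object of class `fold_assignment`: `fold` (integer in
#'   `1..k` per subject), `k`, `seed`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2")
  if (k > min(table(labels)))
    stop("'k' exceeds the smaller class count (", min(table(labels)), ")")
  fold <- integer(length(labels))
  totals <- integer(k)
  with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- sample(which(labels == cls))
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      quota <- rep(base, k)
      if (extra > 0) {
        recipients <- order(totals, seq_len(k))[seq_len(extra)]
        quota[recipients] <- quota[recipients] + 1L
      }
      fold[idx] <- rep(seq_len(k), quota)
      totals <- totals + quota
    }
  })
  structure(list(fold = fold, k = k, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Cross-validated evaluation of one SVM parameter set
#'
#' For each fold: fit the `[-1, 1]` min-max scaling and the SVM on the
#' training rows only, then predict the held-out rows. By default the
#' held-out predictions of all folds are pooled into a single confusion
#' table (`pooled = FALSE` instead averages the per-fold metrics), and the
#' pooled counts always sum to the number of subjects.
#'
#' @param m A [subject_matrix()] (restricted to the active voxels).
#' @param params One row of [svm_param_grid()].
#' @param folds A [stratified_folds()] assignment for `m`'s rows.
#' @param pooled Pool held-out predictions (default) or average per-fold
#'   metrics.
#' @return A `metrics_report`.
#' @export
cross_validate <- function(m, params, folds, pooled = TRUE) {
  stopifnot(inherits(m, "subject_matrix"))
  if (length(folds$fold) != nrow(m$values))
    stop("fold assignment does not match the subject matrix")
  y <- m$labels
  pred <- character(length(y))
  per_fold <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test <- folds$fold == f
    if (nlevels(droplevels(y[!test])) < 2L)
      stop("training fold ", f, " is missing a class")
    sc <- minmax_fit(m$values[!test, , drop = FALSE])
    fit <- train_svm(minmax_apply(m$values[!test, , drop = FALSE], sc),
                     y[!test], params)
    p <- as.character(stats::predict(
      fit, minmax_apply(m$values[test, , drop = FALSE], sc)))
    pred[test] <- p
    if (!pooled)
      per_fold[[f]] <- confusion_metrics(y[test], p, m$positive_class)
  }
  if (pooled) return(confusion_metrics(y, pred, m$positive_class))
  avg <- colMeans(do.call(rbind, lapply(per_fold, as_metrics_row)))
  pooledc <- confusion_metrics(y, pred, m$positive_class)
  out <- pooledc
  for (nm in c("precision", "recall", "f_measure", "sensitivity",
               "specificity"))
    out[[nm]] <- avg[[nm]]
  out
}

#' Leave-one-out evaluation
#'
#' The exhaustive `k = N` case: `N` fits, each holding out exactly one
#' subject, with the confusion table pooled over the `N` held-out
#' predictions. Equivalent to [cross_validate()] with one fold per subject,
#' and invariant to subject ordering.
#'
#' @param m A [subject_matrix()].
#' @param params One row of [svm_param_grid()].
#' @return A `metrics_report`.
#' @export
loo_validate <- function(m, params) {
  n <- nrow(m$values)
  if (n < 3L) stop("leave-one-out needs at least 3 subjects")
  folds <- structure(list(fold = seq_len(n), k = n, seed = NA_integer_),
                     class = "fold_assignment")
  cross_validate(m, params, folds, pooled = TRUE)
}

#' Select the best record by F-measure with recall tie-break
#'
#' Argmax by F-measure; among equal F-measures the highest recall wins;
#' remaining ties go to the earliest record (enumeration order).
#'
#' @param f_measure,recall Numeric vectors of equal length (one entry per
#'   candidate record).
#' @return Index of the winning record.
#' @export
select_best <- function(f_measure, recall) {
  if (length(f_measure) == 0L) stop("no records to select from")
  if (length(f_measure) != length(recall))
    stop("'f_measure' and 'recall' lengths differ")
  best_f <- max(f_measure)
  cand <- which(f_measure == best_f)
  cand[which.max(recall[cand])]
}
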