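#' Fit the spatially constrained SVM-RFE classifier
#'
#' The package's main estimator. Starting from a subjects-by-voxels matrix,
#' the procedure (optionally) discards voxels with zero information gain,
#' then iterates: (1) cluster the active voxels on the lattice with
#' [grid_dbscan()] and drop clusters smaller than `min_cluster_size`
#' ([size_filter()]); (2) evaluate every SVM parameter set of `grid` by
#' `cv_folds`-fold cross-validated F-measure on the active voxels and keep
#' the best (recall tie-break); (3) rank voxels by linear-SVM weight
#' magnitude ([linear_rank_weights()]) and eliminate the `R` weakest
#' ([rfe_step()]). The loop ends after the evaluation at which no more than
#' `R` voxels remain, or as soon as clustering (or the information-gain
#' filter) leaves no voxel. The best iteration maximizes the
#' cross-validated F-measure, with ties broken by recall and then by the
#' earliest iteration (the largest spatially supported voxel set).
#'
#' By default feature selection sees all subjects and cross-validation is
#' used only to score parameter sets — the classical, leakage-prone protocol
#' whose optimism [nested_cv()] quantifies.
#'
#' @param m A [subject_matrix()], whole-brain normalized.
#' @param R Number of voxels eliminated per iteration.
#' @param params A [dbscan_params()] (adjacency and cluster-size threshold).
#' @param grid SVM parameter grid, as from [svm_param_grid()].
#' @param cv_folds Folds for the model-selection cross-validation.
#' @param seed Integer seed (drives the fold assignment).
#' @param rank_C Cost of the linear ranking SVM.
#' @param apply_ig Run the [ig_filter()] screen first (default `TRUE`).
#' @return An object of class `voxrfe`: `trace` (per-iteration data frame),
#'   `active_history` (per-iteration active column indices into `m`),
#'   `best_iteration`, `best_columns`, `best_coords`, `best_params`,
#'   `best_labeling`, `model` (final SVM refitted on all subjects at the
#'   best voxels), `scaling`, `ig` (the `ig_result` or `NULL`), `status`
#'   (`"ok"`, `"no_voxels_after_ig"` or `"no_clusters"`), plus the call.
#' @seealso [voxrfe_evaluate()], [nested_cv()], [cluster_report()]
#' @export
voxrfe <- function(m, R = 100L, params = dbscan_params(),
                   grid = svm_param_grid(), cv_folds = 10L, seed = 1L,
                   rank_C = 1, apply_ig = TRUE) {
  stopifnot(inherits(m, "subject_matrix"))
  cl <- match.call()
  ig <- NULL
  active <- seq_len(ncol(m$values))
  if (apply_ig) {
    ig <- ig_filter(m)
    active <- ig$selected
    if (length(active) == 0L)
      return(new_voxrfe(cl, m, trace = empty_trace(), active_history = list(),
                        ig = ig, status = "no_voxels_after_ig"))
  }
  folds <- stratified_folds(m$labels, cv_folds, seed = seed)
  trace <- list(); active_history <- list(); labelings <- list()
  status <- "ok"
  repeat {
    lab <- grid_dbscan(m$coords[active, , drop = FALSE], params)
    sf <- size_filter(lab, params$min_cluster_size)
    if (length(sf$retained) == 0L) {
      status <- if (length(trace)) "ok" else "no_clusters"
      break
    }
    active <- active[sf$retained]
    sub <- sm_subset(m, active)
    scores <- lapply(seq_len(nrow(grid)), function(i)
      cross_validate(sub, grid[i, , drop = FALSE], folds))
    best <- select_best(vapply(scores, `[[`, 0, "f_measure"),
                        vapply(scores, `[[`, 0, "recall"))
    it <- length(trace) + 1L
    trace[[it]] <- cbind(
      data.frame(iteration = it, n_voxels = length(active),
                 n_clusters = length(sf$labeling$sizes)),
      grid[best, , drop = FALSE],
      as_metrics_row(scores[[best]]))
    active_history[[it]] <- active
    labelings[[it]] <- sf$labeling
    if (length(active) <= R) break
    w <- linear_rank_weights(
      minmax_scale(sub$values)$train, sub$labels, cost = rank_C)
    keep <- rfe_step(w, R)
    if (length(keep) == 0L) break
    active <- active[keep]
  }
  if (length(trace) == 0L)
    return(new_voxrfe(cl, m, trace = empty_trace(), active_history = list(),
                      ig = ig, status = status))
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  cand <- which(trace$f_measure == max(trace$f_measure))
  cand <- cand[trace$recall[cand] == max(trace$recall[cand])]
  best_it <- cand[1L]
  best_columns <- active_history[[best_it]]
  best_sub <- sm_subset(m, best_columns)
  scaling <- minmax_fit(best_sub$values)
  param_cols <- c("kernel", "svm_type", "degree", "cost", "gamma", "coef0",
                  "nu")
  best_params <- trace[best_it, param_cols, drop = FALSE]
  rownames(best_params) <- NULL
  model <- train_svm(minmax_apply(best_sub$values, scaling), best_sub$labels,
                     best_params)
  new_voxrfe(cl, m, trace = trace, active_history = active_history,
             ig = ig, status = status, best_iteration = best_it,
             best_columns = best_columns, best_coords = best_sub$coords,
             best_params = best_params,
             best_labeling = labelings[[best_it]], model = model,
             scaling = scaling, best_values = best_sub$values)
}

empty_trace <- function() {
  cbind(data.frame(iteration = integer(0), n_voxels = integer(0),
                   n_clusters = integer(0)),
        svm_param_grid()[0, ],
        data.frame(tp = integer(0), fp = integer(0), tn = integer(0),
                   fn = integer(0), precision = numeric(0),
                   recall = numeric(0), f_measure = numeric(0),
                   sensitivity = numeric(0), specificity = numeric(0)))
}

new_voxrfe <- function(call, m, trace, active_history, ig, status,
                       best_iteration = NA_integer_, best_columns = integer(0),
                       best_coords = matrix(integer(0), 0, 3),
                       best_params = NULL, best_labeling = NULL,
                       model = NULL, scaling = NULL, best_values = NULL) {
  structure(list(call = call, trace = trace, active_history = active_history,
                 ig = ig, status = status, best_iteration = best_iteration,
                 best_columns = best_columns, best_coords = best_coords,
                 best_params = best_params, best_labeling = best_labeling,
                 model = model, scaling = scaling, best_values = best_values,
                 labels = m$labels, positive_class = m$positive_class,
                 geometry = m$geometry, n_input_voxels = ncol(m$values)),
            class = "voxrfe")
}

#' @export
print.voxrfe <- function(x, ...) {
  cat("Spatially constrained SVM-RFE fit\n")
  cat(sprintf("  input: %d subjects x %d voxels\n", length(x$labels),
              x$n_input_voxels))
  if (!is.null(x$ig))
    cat(sprintf("  information-gain survivors: %d\n", length(x$ig$selected)))
  if (x$status != "ok") {
    cat(sprintf("  terminated early: %s\n", x$status))
    return(invisible(x))
  }
  cat(sprintf("  iterations: %d; best iteration %d with %d voxels in %d cluster(s)\n",
              nrow(x$trace), x$best_iteration,
              x$trace$n_voxels[x$best_iteration],
              x$trace$n_clusters[x$best_iteration]))
  cat(sprintf("  best parameters: %s\n",
              param_string(x$best_params)))
  cat(sprintf("  selection CV F-measure: %.3f (recall %.3f)\n",
              x$trace$f_measure[x$best_iteration],
              x$trace$recall[x$best_iteration]))
  invisible(x)
}

#' @export
summary.voxrfe <- function(object, ...) {
  print(object)
  if (object$status == "ok") {
    cat("\nIteration trace:\n")
    print(object$trace[, c("iteration", "n_voxels", "n_clusters", "kernel",
                           "svm_type", "f_measure", "recall", "precision",
                           "specificity")], row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.voxrfe <- function(object, ...) {
  if (object$status != "ok") stop("fit has no selected voxels")
  w <- linear_rank_weights(
    minmax_apply(object$best_values, object$scaling), object$labels)
  names(w) <- apply(object$best_coords, 1, paste, collapse = ",")
  w
}

#' Predict group membership for new subjects
#'
#' Applies the stored `[-1, 1]` scaling (fitted on the training cohort) and
#' the final SVM to the best-voxel columns of `newdata`. `newdata` must be
#' on the same grid: its coordinates must contain every selected voxel.
#'
#' @param object A fitted [voxrfe()] object.
#' @param newdata A [subject_matrix()] (same mask/column order), or a plain
#'   matrix whose columns already correspond to the selected voxels.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.voxrfe <- function(object, newdata, ...) {
  if (object$status != "ok") stop("fit has no usable model")
  x <- if (inherits(newdata, "subject_matrix")) {
    idx <- match(
      do.call(paste, as.data.frame(object$best_coords)),
      do.call(paste, as.data.frame(newdata$coords)))
    if (any(is.na(idx)))
      stop("'newdata' does not contain all selected voxels")
    newdata$values[, idx, drop = FALSE]
  } else {
    as.matrix(newdata)
  }
  if (ncol(x) != length(object$best_columns))
    stop("'newdata' must provide one column per selected voxel")
  stats::predict(object$model, minmax_apply(x, object$scaling))
}

#' Plot the model-selection trajectory
#'
#' Cross-validated F-measure against the number of active voxels, one point
#' per elimination iteration, with the selected iteration highlighted.
#'
#' @param x A fitted [voxrfe()] object.
#' @param ... Passed to [plot.default()].
#' @export
plot.voxrfe <- function(x, ...) {
  if (x$status != "ok" || nrow(x$trace) == 0L) stop("nothing to plot")
  tr <- x$trace
  plot(tr$n_voxels, tr$f_measure, type = "b", pch = 16,
       xlab = "active voxels", ylab = "cross-validated F-measure",
       xlim = rev(range(tr$n_voxels)), ...)
  graphics::points(tr$n_voxels[x$best_iteration],
                   tr$f_measure[x$best_iteration],
                   pch = 1, cex = 2.2, col = 2)
  invisible(x)
}

#' Evaluate the selected model: training, k-fold and leave-one-out
#'
#' Re-evaluates the best parameter set on the best voxel subset three ways:
#' on the full training cohort (the "model" accuracy), by stratified k-fold
#' cross-validation, and by leave-one-out. Scaling is always refitted
#' inside each training split.
#'
#' @param object A fitted [voxrfe()] object.
#' @param m The [subject_matrix()] the fit came from.
#' @param cv_folds Folds for the k-fold report.
#' @param seed Seed for the fold assignment.
#' @param loo Also run leave-one-out (default `TRUE`).
#' @return List of `metrics_report`s: `model`, `cv`, and `loo` (or `NULL`).
#' @export
voxrfe_evaluate <- function(object, m, cv_folds = 10L, seed = 1L,
                            loo = TRUE) {
  stopifnot(inherits(object, "voxrfe"), inherits(m, "subject_matrix"))
  if (object$status != "ok") stop("fit has no selected voxels")
  sub <- sm_subset(m, object$best_columns)
  params <- object$best_params
  train_pred <- stats::predict(
    object$model, minmax_apply(sub$values, object$scaling))
  list(model = confusion_metrics(m$labels, train_pred, m$positive_class),
       cv = cross_validate(sub, params,
                           stratified_folds(m$labels, cv_folds, seed = seed)),
       loo = if (loo) loo_validate(sub, params) else NULL)
}

#' Nested cross-validation of the whole selection pipeline
#'
#' Runs the complete [voxrfe()] selection (information-gain filter,
#' clustering, elimination, grid search) inside each training fold and
#' predicts the corresponding held-out subjects, so the reported metrics
#' are free of feature-selection leakage. This is the honest estimate of
#' generalization; the default protocol's figures are optimistic because
#' selection sees all subjects.
#'
#' @param m A [subject_matrix()].
#' @param outer_folds Number of outer folds.
#' @param seed Seed for the outer fold assignment (inner fits use
#'   `seed + fold`).
#' @param ... Passed on to [voxrfe()].
#' @return List with `metrics` (pooled held-out `metrics_report`) and
#'   `fits` (the per-fold `voxrfe` objects). Folds in which no voxel
#'   survives selection fall back to majority-class prediction.
#' @export
nested_cv <- function(m, outer_folds = 5L, seed = 1L, ...) {
  stopifnot(inherits(m, "subject_matrix"))
  folds <- stratified_folds(m$labels, outer_folds, seed = seed)
  pred <- character(length(m$labels))
  fits <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test <- folds$fold == f
    train_m <- m
    train_m$values <- m$values[!test, , drop = FALSE]
    train_m$labels <- droplevels(m$labels[!test])
    train_m$subject_ids <- m$subject_ids[!test]
    fit <- voxrfe(train_m, seed = seed + f, ...)
    fits[[f]] <- fit
    if (fit$status == "ok") {
      pred[test] <- as.character(
        predict(fit, m$values[test, fit$best_columns, drop = FALSE]))
    } else {
      ## majority-class fallback; exact ties alternate by fold so the
      ## fallback is unbiased across folds
      tab <- table(train_m$labels)
      maj <- if (length(unique(tab)) == 1L)
        names(tab)[1L + (f %% length(tab))] else names(which.max(tab))
      pred[test] <- maj
    }
  }
  list(metrics = confusion_metrics(m$labels, pred, m$positive_class),
       fits = fits)
}
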