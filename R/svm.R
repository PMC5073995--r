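#' Enumerate the SVM parameter search grid
#'
#' Builds the full Cartesian grid over kernels, SVM formulations and their
#' hyperparameters, keeping only the parameters relevant to each kernel /
#' formulation pair (linear: cost or nu; radial: gamma; polynomial: degree,
#' gamma, coef0; sigmoid: gamma, coef0) with irrelevant fields set to `NA`.
#' The order is deterministic and duplicates are impossible by
#' construction, so grid row numbers are stable identifiers and the
#' first-encountered rule of [select_best()] is reproducible.
#'
#' @param kernels Subset of `c("linear", "radial", "polynomial", "sigmoid")`.
#' @param svm_types Subset of `c("C_SVM", "nu_SVM")`.
#' @param cost,gamma,degree,coef0,nu Candidate values for each parameter.
#' @return A `data.frame` with columns `kernel`, `svm_type`, `degree`,
#'   `cost`, `gamma`, `coef0`, `nu`; one row per parameter combination.
#' @examples
#' nrow(svm_param_grid(kernels = "linear", svm_types = "C_SVM"))  # 6
#' @export
svm_param_grid <- function(kernels = c("linear", "radial", "polynomial",
                                       "sigmoid"),
                           svm_types = c("C_SVM", "nu_SVM"),
                           cost = c(2, 4, 10, 12, 15, 20),
                           gamma = c(0.001, 0.003, 0.01, 0.03, 0.05, 0.1),
                           degree = c(3, 4, 5, 6, 7),
                           coef0 = c(0.01, 0.1, 1, 5, 10, 15, 20),
                           nu = c(0.2, 0.29, 0.4, 0.5)) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  svm_types <- match.arg(svm_types, several.ok = TRUE)
  rows <- list()
  for (kern in kernels) {
    g <- if (kern == "linear") NA_real_ else gamma
    d <- if (kern == "polynomial") degree else NA_real_
    c0 <- if (kern %in% c("polynomial", "sigmoid")) coef0 else NA_real_
    for (type in svm_types) {
      reg <- if (type == "C_SVM")
        data.frame(cost = cost, nu = NA_real_)
      else data.frame(cost = NA_real_, nu = nu)
      base <- expand.grid(degree = d, gamma = g, coef0 = c0,
                          reg_row = seq_len(nrow(reg)),
                          KEEP.OUT.ATTRS = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(kernel = kern, svm_type = type,
                   degree = base$degree, cost = reg$cost[base$reg_row],
                   gamma = base$gamma, coef0 = base$coef0,
                   nu = reg$nu[base$reg_row],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## One grid row -> argument list for e1071::svm().
svm_args <- function(params) {
  stopifnot(is.data.frame(params), nrow(params) == 1L)
  a <- list(kernel = params$kernel,
            type = if (params$svm_type == "C_SVM") "C-classification"
                   else "nu-classification",
            scale = FALSE)
  if (!is.na(params$cost)) a$cost <- params$cost
  if (!is.na(params$nu)) a$nu <- params$nu
  if (!is.na(params$gamma)) a$gamma <- params$gamma
  if (!is.na(params$degree)) a$degree <- params$degree
  if (!is.na(params$coef0)) a$coef0 <- params$coef0
  a
}

param_string <- function(params) {
  vals <- unlist(params[1, c("degree", "cost", "gamma", "coef0", "nu")])
  paste0(params$kernel, "/", params$svm_type,
         paste0(ifelse(is.na(vals), "",
                       paste0(" ", names(vals), "=", vals)), collapse = ""))
}

#' Train one SVM at a grid point
#'
#' Thin wrapper around the libsvm binding ([e1071::svm()]): classes are
#' assigned by the sign of the decision function; the polynomial kernel has
#' the form `(gamma * <x, x'> + coef0)^degree`. Features are expected
#' already scaled to the `[-1, 1]` convention (see [minmax_scale()]); no
#' internal rescaling is applied. Solver failures are re-raised with the
#' offending parameter set attached.
#'
#' @param x Numeric matrix, rows = subjects.
#' @param labels Two-class factor; both classes must be present.
#' @param params One row of [svm_param_grid()].
#' @return The fitted `svm` model, with the grid row attached as attribute
#'   `"params"`.
#' @export
train_svm <- function(x, labels, params) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("training labels must contain both classes")
  fit <- tryCatch(
    do.call(e1071::svm, c(list(x = as.matrix(x), y = labels), svm_args(params))),
    error = function(e)
      stop("SVM training failed for ", param_string(params), ": ",
           conditionMessage(e), call. = FALSE))
  attr(fit, "params") <- params
  fit
}

#' Linear SVM weight vector for feature ranking
#'
#' Fits a linear C-SVM on all active voxels and returns the primal weight
#' vector `w`; the magnitude `|w_j|` scores the contribution of voxel `j`
#' to the decision and drives the recursive elimination. Columns that are
#' constant after scaling receive weight 0.
#'
#' @param x Scaled numeric matrix.
#' @param labels Two-class factor.
#' @param cost Cost parameter of the ranking SVM (default 1).
#' @return Numeric weight vector, one entry per column of `x`.
#' @export
linear_rank_weights <- function(x, labels, cost = 1) {
  params <- data.frame(kernel = "linear", svm_type = "C_SVM",
                       degree = NA_real_, cost = cost, gamma = NA_real_,
                       coef0 = NA_real_, nu = NA_real_)
  fit <- train_svm(x, labels, params)
  as.vector(crossprod(fit$coefs, fit$SV))
}

#' One recursive-feature-elimination step
#'
#' Drops the `R` features with the smallest weight magnitudes `|w_j|`, ties
#' broken by ascending column index (the earlier column is dropped first);
#' survivors keep their original order. If `R >= length(w)` no feature
#' survives.
#'
#' @param w Numeric weight vector.
#' @param R Number of features to eliminate (>= 1).
#' @return Integer indices of the surviving columns, in original order.
#' @examples
#' rfe_step(c(0.9, -0.1, 0.5, 0.05), 2)  # 1 and 3 survive
#' @export
rfe_step <- function(w, R = 100L) {
  if (R < 1L) stop("'R' must be >= 1")
  n <- length(w)
  if (R >= n) return(integer(0))
  drop_idx <- order(abs(w), seq_len(n))[seq_len(R)]
  setdiff(seq_len(n), drop_idx)
}
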