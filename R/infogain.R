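#' Information gain of one voxel under MDL-stopped discretization
#'
#' Computes the information gain (in bits) of a continuous feature for a
#' two-class label: the class entropy minus the class entropy conditional on
#' a supervised binning of the feature values. Bins come from recursive
#' binary splitting on the sorted values: at each step the cut point (always
#' between distinct values, so ties share a bin) maximizing the entropy gain
#' is accepted only if it passes the minimum-description-length stopping
#' criterion of Fayyad and Irani; both sides are then split recursively. If
#' no cut is ever accepted the feature is binned into a single interval and
#' the information gain is exactly 0 — the behaviour that lets the filter
#' discard the vast majority of voxels.
#'
#' The result depends only on the ordering of the values, so it is invariant
#' under strictly monotone transforms, and lies in `[0, H(class)]`.
#'
#' @param values Numeric vector, one value per subject.
#' @param labels Two-class factor (or coercible) of the same length; both
#'   classes must be present.
#' @return Information gain in bits (scalar >= 0).
#' @examples
#' information_gain(c(1, 2, 3, 4, 11, 12, 13, 14), rep(c("a", "b"), each = 4))
#' @export
information_gain <- function(values, labels) {
  y <- as.integer(as.factor(labels))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (length(values) != length(y)) stop("'values' and 'labels' lengths differ")
  o <- order(values)
  ys <- y[o]
  ## cumulative count of class 1 along the sorted values
  c1 <- cumsum(ys == 1L)
  ## cut admissible only between distinct adjacent values
  xs <- values[o]
  cuttable <- xs[-length(xs)] < xs[-1L]
  n <- length(ys)
  cond <- ig_recurse(1L, n, c1, cuttable)
  max(0, ent_bits(c1[n], n) - cond / n)   # clamp tiny negative round-off
}

## Binary entropy (bits) of a 2-class count split: n1 of n.
ent_bits <- function(n1, n) {
  p <- n1 / n
  q <- 1 - p
  -ifelse(p > 0, p * log2(p), 0) - ifelse(q > 0, q * log2(q), 0)
}

## Recursive MDL splitting over the sorted range [lo, hi] (1-based,
## inclusive).  Returns sum over final bins of n_bin * H(class | bin).
ig_recurse <- function(lo, hi, c1, cuttable) {
  n <- hi - lo + 1L
  n1 <- c1[hi] - if (lo > 1L) c1[lo - 1L] else 0L
  h <- ent_bits(n1, n)
  if (hi == lo || h == 0) return(n * h)
  cuts <- which(cuttable[lo:(hi - 1L)])
  if (length(cuts) == 0L) return(n * h)
  i <- lo + cuts - 1L                          # cut after position i
  nl <- i - lo + 1L
  n1l <- c1[i] - if (lo > 1L) c1[lo - 1L] else 0L
  hl <- ent_bits(n1l, nl)
  hr <- ent_bits(n1 - n1l, n - nl)
  gain <- h - (nl * hl + (n - nl) * hr) / n
  best <- which.max(gain)
  ## Fayyad-Irani MDL acceptance: gain must exceed
  ## (log2(n-1) + log2(3^k - 2) - (k*H - k1*H1 - k2*H2)) / n
  nl_b <- nl[best]; n1l_b <- n1l[best]
  k <- (n1 > 0L) + (n1 < n)
  kl <- (n1l_b > 0L) + (n1l_b < nl_b)
  kr <- ((n1 - n1l_b) > 0L) + ((n1 - n1l_b) < (n - nl_b))
  delta <- log2(3^k - 2) - (k * h - kl * hl[best] - kr * hr[best])
  thresh <- (log2(n - 1) + delta) / n
  if (gain[best] <= thresh) return(n * h)
  cut_at <- i[best]
  ig_recurse(lo, cut_at, c1, cuttable) + ig_recurse(cut_at + 1L, hi, c1, cuttable)
}

#' Information-gain voxel filter
#'
#' Applies [information_gain()] to every column of a subject matrix and
#' retains the voxels with strictly positive gain, preserving column order.
#' When no voxel survives, the result carries zero selected columns and
#' callers are expected to stop with a clear message (the fitted pipeline
#' does).
#'
#' @param m A [subject_matrix()].
#' @return An object of class `ig_result`: `ig_bits` (per-column gain),
#'   `selected` (surviving column indices), `class_priors` (named
#'   two-element vector) and `n_total`.
#' @export
ig_filter <- function(m) {
  y <- m$labels
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  ig <- numeric(ncol(m$values))
  maybe <- ig_root_screen(m$values, y)
  for (j in which(maybe))
    ig[j] <- information_gain(m$values[, j], y)
  pri <- as.vector(table(y)) / length(y)
  names(pri) <- levels(y)
  structure(list(ig_bits = ig, selected = which(ig > 0),
                 class_priors = pri, n_total = ncol(m$values)),
            class = "ig_result")
}

## Vectorized screen deciding, for every column at once, whether the root
## split is MDL-accepted.  Columns failing the screen have information gain
## exactly 0 (the recursion never starts), so only the accepted ones need
## the full per-column recursion.  Replicates the scalar decision exactly,
## including the first-maximum tie rule.
ig_root_screen <- function(X, labels) {
  M <- nrow(X); n <- ncol(X)
  if (M < 2L) return(rep(FALSE, n))
  y1 <- as.integer(as.factor(labels)) == 1L
  idx <- order(col(X), X)              # within-column ascending order
  xs <- matrix(X[idx], M, n)
  ysm <- matrix(y1[((idx - 1L) %% M) + 1L], M, n)
  L <- matrix(0, M, M); L[lower.tri(L, diag = TRUE)] <- 1
  c1 <- L %*% ysm                      # cumulative class-1 counts
  a <- sum(y1)                         # root class-1 count (both present)
  h <- ent_bits(a, M)
  i <- seq_len(M - 1L)
  nl <- matrix(i, M - 1L, n)
  n1l <- c1[i, , drop = FALSE]
  ## entropy lookup over all (count, size) pairs beats elementwise ifelse
  ent_tab <- outer(0:M, 1:M, function(n1, nn) {
    p <- pmin(pmax(n1 / nn, 0), 1)
    -ifelse(p > 0, p * log2(p), 0) - ifelse(p < 1, (1 - p) * log2(1 - p), 0)
  })
  lk <- function(cnt, size) matrix(ent_tab[cbind(c(cnt) + 1L, c(size))],
                                   M - 1L, n)
  hl <- lk(n1l, nl)
  hr <- lk(a - n1l, M - nl)
  gain <- h - (nl * hl + (M - nl) * hr) / M
  gain[xs[i + 1L, , drop = FALSE] <= xs[i, , drop = FALSE]] <- -Inf
  best <- max.col(t(gain), ties.method = "first")
  sel <- cbind(best, seq_len(n))
  bg <- gain[sel]
  nl_b <- best
  n1l_b <- n1l[sel]
  kl <- (n1l_b > 0) + (n1l_b < nl_b)
  kr <- ((a - n1l_b) > 0) + ((a - n1l_b) < (M - nl_b))
  delta <- log2(3^2 - 2) - (2 * h - kl * hl[sel] - kr * hr[sel])
  is.finite(bg) & bg > (log2(M - 1) + delta) / M
}

#' @export
print.ig_result <- function(x, ...) {
  cat(sprintf("<ig_result> %d of %d voxels with IG > 0 (max %.3f bits)\n",
              length(x$selected), x$n_total,
              if (length(x$ig_bits)) max(x$ig_bits) else 0))
  invisible(x)
}

#' Lilliefors normality screen (descriptive)
#'
#' Tests every voxel for normality within each class using the Lilliefors
#' (Kolmogorov-Smirnov with estimated mean and variance) test; a voxel
#' counts as normal only when the test fails to reject in both classes.
#' Zero-variance voxels are treated as rejections. The screen is purely
#' descriptive — it motivates the use of a non-parametric voxel filter and
#' rank tests, and never gates the pipeline.
#'
#' @param m A [subject_matrix()] with at least 5 subjects per class.
#' @param alpha Per-test significance level.
#' @return List with `fraction_normal` (scalar) and `normal_mask` (logical
#'   per voxel).
#' @export
normality_screen <- function(m, alpha = 0.05) {
  y <- droplevels(m$labels)
  if (any(table(y) < 5L)) stop("need at least 5 subjects per class")
  groups <- split(seq_along(y), y)
  normal <- rep(TRUE, ncol(m$values))
  for (g in groups) {
    for (j in which(normal)) {
      v <- m$values[g, j]
      if (stats::sd(v) == 0) {
        normal[j] <- FALSE
      } else {
        normal[j] <- nortest::lillie.test(v)$p.value >= alpha
      }
    }
  }
  list(fraction_normal = mean(normal), normal_mask = normal)
}
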