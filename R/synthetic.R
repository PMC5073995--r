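#' Configuration for a synthetic two-group cohort
#'
#' Full recipe for a reproducible cohort of smooth, positive, rCBF-like 3D
#' volumes in which a small number of spatially compact clusters differ in
#' mean intensity between the positive group and controls. Each subject
#' volume is built as
#' `baseline_mean * (1 + s * effect_size * 1[effect cluster]) + N(0, noise_sigma)`,
#' then Gaussian-smoothed to `smooth_fwhm_vox` FWHM, masked and flattened;
#' `s` is the planted cluster sign for positive-class subjects and 0 for
#' controls.
#'
#' Defaults emulate a perfusion-map study at acquisition resolution: a
#' 40 x 48 x 35 grid of 4 mm voxels (the standard MNI field of view),
#' smoothing to 10 mm FWHM (2.5 voxels), a baseline of 50 (the order of
#' grey-matter rCBF in ml/100g/min), raw voxel noise of 30 (which the
#' smoothing reduces to roughly 8% between-subject variability), and a 15%
#' regional effect.
#'
#' @param shape Integer triple of grid dimensions.
#' @param voxel_size_mm Real triple of voxel sizes (mm).
#' @param mask_kind `"ellipsoid"` or `"full_box"` (see [make_mask()]).
#' @param n_pos,n_ctrl Subjects per group (>= 1).
#' @param n_effect_clusters Number of planted clusters (>= 0).
#' @param cluster_radius_vox Ball radius of each planted cluster, voxels.
#' @param effect_size Multiplicative mean shift (0.15 = 15%).
#' @param effect_sign_mix Probability that a planted cluster has a positive
#'   (hyper-intensity) shift in the positive class.
#' @param noise_sigma Standard deviation of the additive voxel noise before
#'   smoothing.
#' @param smooth_fwhm_vox Gaussian smoothing kernel full width at half
#'   maximum, in voxels (0 disables smoothing).
#' @param baseline_mean Positive baseline intensity.
#' @param seed Integer RNG seed; the whole cohort is a pure function of the
#'   config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(shape = c(40, 48, 35), voxel_size_mm = c(4, 4, 4),
                         mask_kind = c("ellipsoid", "full_box"),
                         n_pos = 20, n_ctrl = 20, n_effect_clusters = 3,
                         cluster_radius_vox = 3, effect_size = 0.15,
                         effect_sign_mix = 0.9, noise_sigma = 30,
                         smooth_fwhm_vox = 2.5, baseline_mean = 50,
                         seed = 1) {
  cfg <- list(shape = as.integer(shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              mask_kind = match.arg(mask_kind),
              n_pos = as.integer(n_pos), n_ctrl = as.integer(n_ctrl),
              n_effect_clusters = as.integer(n_effect_clusters),
              cluster_radius_vox = as.integer(cluster_radius_vox),
              effect_size = as.numeric(effect_size),
              effect_sign_mix = as.numeric(effect_sign_mix),
              noise_sigma = as.numeric(noise_sigma),
              smooth_fwhm_vox = as.numeric(smooth_fwhm_vox),
              baseline_mean = as.numeric(baseline_mean),
              seed = as.integer(seed))
  if (cfg$n_pos < 1L || cfg$n_ctrl < 1L) stop("need >= 1 subject per group")
  if (cfg$n_effect_clusters < 0L) stop("'n_effect_clusters' must be >= 0")
  if (cfg$cluster_radius_vox < 1L) stop("'cluster_radius_vox' must be >= 1")
  if (cfg$noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (cfg$smooth_fwhm_vox < 0) stop("'smooth_fwhm_vox' must be >= 0")
  if (cfg$baseline_mean <= 0) stop("'baseline_mean' must be positive")
  if (cfg$effect_sign_mix < 0 || cfg$effect_sign_mix > 1)
    stop("'effect_sign_mix' must be in [0, 1]")
  structure(cfg, class = "synth_config")
}

## Evaluate expr with a private RNG stream; the caller's RNG state is
## untouched and the result depends only on `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## All lattice offsets within Euclidean distance `radius` of the origin.
ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Plant disjoint ball-shaped effect clusters inside a mask
#'
#' Seeds `n_effect_clusters` centres uniformly over the mask interior,
#' keeping only placements whose full ball (lattice voxels within Euclidean
#' distance `cluster_radius_vox` of the centre) lies inside the mask and
#' does not touch a previously placed ball. A radius-2 ball has 33 voxels,
#' so any planted cluster with radius >= 2 survives the pipeline's 20-voxel
#' retention threshold. Cluster signs are drawn per `effect_sign_mix`.
#'
#' @param mask A [brain_mask()].
#' @param cfg A [synth_config()].
#' @return An object of class `ground_truth`: list of per-cluster coordinate
#'   matrices (`clusters`), per-cluster signs (`signs`, +1/-1), the union
#'   coordinate matrix (`effect_voxels`), and `config`.
#' @export
plant_clusters <- function(mask, cfg) {
  with_seed(cfg$seed, plant_clusters_impl(mask, cfg))
}

plant_clusters_impl <- function(mask, cfg) {
  k <- cfg$n_effect_clusters
  out <- list(clusters = list(), signs = integer(0))
  if (k > 0) {
    offs <- ball_offsets(cfg$cluster_radius_vox)
    cand <- mask_coords(mask)         # 0-based
    shape <- mask$geometry$shape
    taken_keys <- numeric(0)
    ## forbid adjacency between planted balls so they remain distinct
    ## connected components under the <= sqrt(2) lattice adjacency
    guard <- ball_offsets(cfg$cluster_radius_vox + 1L)
    tries <- 0L; max_tries <- 500L * k
    while (length(out$clusters) < k) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", k, " disjoint clusters of radius ",
             cfg$cluster_radius_vox, "; use a larger mask")
      ctr <- cand[sample.int(nrow(cand), 1L), ]
      ball <- sweep(offs, 2, ctr, "+")
      if (any(ball < 0) ||
          any(ball >= matrix(shape, nrow(ball), 3, byrow = TRUE)))
        next
      if (!all(mask$inside[ball + 1L])) next
      guard_keys <- vox_key(sweep(guard, 2, ctr, "+"), shape)
      if (any(guard_keys %in% taken_keys)) next
      out$clusters[[length(out$clusters) + 1L]] <- ball
      taken_keys <- c(taken_keys, vox_key(ball, shape))
    }
    out$signs <- ifelse(stats::runif(k) < cfg$effect_sign_mix, 1L, -1L)
  }
  effect <- if (length(out$clusters)) do.call(rbind, out$clusters) else
    matrix(integer(0), 0, 3)
  structure(list(clusters = out$clusters, signs = out$signs,
                 effect_voxels = effect, config = cfg),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d planted cluster(s), %d effect voxels (%d+, %d-)\n",
              length(x$clusters), nrow(x$effect_voxels),
              sum(x$signs > 0), sum(x$signs < 0)))
  invisible(x)
}

#' Generate a reproducible synthetic cohort
#'
#' Builds the mask, plants the ground-truth clusters, simulates one volume
#' per subject as described in [synth_config()], and returns the masked,
#' flattened cohort together with the ground truth. Identical configs
#' (including seed) produce bit-identical cohorts.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `matrix` (a [subject_matrix()], labels
#'   `control`/`positive` with `positive` the positive class), `truth`
#'   (a `ground_truth`), and `mask` (the [brain_mask()]).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  geometry <- vox_geometry(cfg$shape, cfg$voxel_size_mm)
  mask <- make_mask(cfg$shape, cfg$mask_kind, geometry)
  truth <- plant_clusters(mask, cfg)

  effect <- array(0, cfg$shape)
  for (i in seq_along(truth$clusters))
    effect[truth$clusters[[i]] + 1L] <- truth$signs[i] * cfg$effect_size

  inside_idx <- which(mask$inside)
  n <- cfg$n_pos + cfg$n_ctrl
  labels <- rep(c("positive", "control"), c(cfg$n_pos, cfg$n_ctrl))
  ids <- c(sprintf("pos%03d", seq_len(cfg$n_pos)),
           sprintf("ctrl%03d", seq_len(cfg$n_ctrl)))
  values <- with_seed(cfg$seed + 1L, {
    v <- matrix(NA_real_, n, length(inside_idx))
    for (i in seq_len(n)) {
      vol <- cfg$baseline_mean *
        (1 + (if (labels[i] == "positive") effect else 0)) +
        array(stats::rnorm(prod(cfg$shape), sd = cfg$noise_sigma), cfg$shape)
      vol <- gauss_smooth(vol, cfg$smooth_fwhm_vox, normalize = "mean")
      v[i, ] <- vol[inside_idx]
    }
    v
  })
  m <- subject_matrix(values, mask_coords(mask),
                      factor(labels, levels = c("control", "positive")),
                      subject_ids = ids, geometry = geometry,
                      positive_class = "positive")
  list(matrix = m, truth = truth, mask = mask)
}

## ---- separable Gaussian smoothing -------------------------------------

## 1D kernel for a given FWHM (voxels), truncated at 4 sigma.
gauss_kernel <- function(fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  stats::dnorm(seq.int(-r, r), sd = sigma)
}

## Dense band matrix applying a 1D convolution along one axis.
conv_band <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    B[i, j] <- kernel[j - i + r + 1L]
  }
  B
}

## Apply axis band matrices S (list of 3) to a 3D array via matrix products.
conv_separable <- function(v, S) {
  d <- dim(v)
  v <- S[[1]] %*% matrix(v, d[1], d[2] * d[3]); dim(v) <- d
  v <- aperm(v, c(2, 1, 3)); dv <- dim(v)
  v <- S[[2]] %*% matrix(v, dv[1], dv[2] * dv[3]); dim(v) <- dv
  v <- aperm(v, c(2, 1, 3))
  v <- aperm(v, c(3, 2, 1)); dv <- dim(v)
  v <- S[[3]] %*% matrix(v, dv[1], dv[2] * dv[3]); dim(v) <- dv
  aperm(v, c(3, 2, 1))
}

## Gaussian-smooth a 3D array.
##   normalize = "mean": kernel weights renormalized at the boundary so a
##     constant array stays constant (used for cohort volumes);
##   normalize = "sd": output divided by the per-voxel standard deviation
##     of smoothed unit white noise, so white-noise input yields an exactly
##     unit-variance field (used by the cluster-extent simulation).
gauss_smooth <- function(v, fwhm_vox, normalize = c("mean", "sd", "none")) {
  normalize <- match.arg(normalize)
  if (fwhm_vox <= 0) return(v)
  k <- gauss_kernel(fwhm_vox)
  d <- dim(v)
  if (normalize == "mean") {
    S1 <- lapply(d, conv_band, kernel = k / sum(k))
    conv_separable(v, S1) / conv_separable(array(1, d), S1)
  } else if (normalize == "sd") {
    S <- lapply(d, conv_band, kernel = k)
    S2 <- lapply(d, conv_band, kernel = k^2)
    conv_separable(v, S) / sqrt(conv_separable(array(1, d), S2))
  } else {
    conv_separable(v, lapply(d, conv_band, kernel = k))
  }
}
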