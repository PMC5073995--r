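#' Parameters of the lattice DBSCAN
#'
#' Defaults encode the edge-sharing neighbourhood on the voxel lattice:
#' `epsilon = sqrt(2)` admits the 6 face-adjacent (distance 1) and 12
#' edge-adjacent (distance sqrt(2)) voxels and excludes the 8 corner-adjacent
#' ones (distance sqrt(3)); `min_pts = 2` (the count includes the voxel
#' itself) makes every voxel with at least one such neighbour a core point,
#' so the clustering equals connected components of the 18-adjacency graph;
#' clusters smaller than `min_cluster_size = 20` voxels are discarded by
#' [size_filter()].
#'
#' @param epsilon Euclidean neighbourhood radius on the lattice (> 0).
#' @param min_pts Minimum neighbourhood count, including the point itself
#'   (>= 1), for a voxel to be a core point.
#' @param min_cluster_size Retention threshold for [size_filter()] (>= 1).
#' @return An object of class `dbscan_params`.
#' @export
dbscan_params <- function(epsilon = sqrt(2), min_pts = 2L,
                          min_cluster_size = 20L) {
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  if (min_pts < 1L) stop("'min_pts' must be >= 1")
  if (min_cluster_size < 1L) stop("'min_cluster_size' must be >= 1")
  structure(list(epsilon = epsilon, min_pts = as.integer(min_pts),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "dbscan_params")
}

## Integer lattice offsets with 0 < squared distance <= eps^2 (bounded to
## the +-ceiling(eps) cube; adequate for the small epsilons used here).
lattice_offsets <- function(epsilon) {
  r <- ceiling(epsilon)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  d2 <- rowSums(g^2)
  g[d2 > 0 & d2 <= epsilon^2 + 1e-9, , drop = FALSE]
}

#' Lattice neighbours of a voxel
#'
#' All voxels of `universe` other than `v` within Euclidean distance
#' `epsilon` of `v`. Under the default `epsilon = sqrt(2)` this is the
#' 18-neighbourhood (faces and edges, not corners).
#'
#' @param v Integer coordinate triple.
#' @param universe Integer matrix (n x 3) of voxel coordinates.
#' @param epsilon Neighbourhood radius.
#' @return Matrix of the neighbouring coordinates (possibly 0 rows).
#' @examples
#' u <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 1, 1))
#' voxel_neighbors(c(0, 0, 0), u)  # only (1, 1, 0)
#' @export
voxel_neighbors <- function(v, universe, epsilon = sqrt(2)) {
  universe <- rbind_coords(universe)
  d2 <- rowSums(sweep(universe, 2, as.numeric(v), "-")^2)
  universe[d2 > 0 & d2 <= epsilon^2 + 1e-9, , drop = FALSE]
}

## Neighbour index matrix (n x n_offsets, NA where absent) for a coordinate
## set, via injective keys and binary search.
neighbor_index <- function(coords, epsilon) {
  n <- nrow(coords)
  lo <- apply(coords, 2, min)
  span <- apply(coords, 2, max) - lo + 1L
  shifted <- sweep(coords, 2, lo, "-")
  key <- vox_key(shifted, span)
  o <- order(key)
  skey <- key[o]
  offs <- lattice_offsets(epsilon)
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    target <- key + vox_key(matrix(offs[j, ], 1), span) -
      vox_key(matrix(c(0, 0, 0), 1), span)
    pos <- findInterval(target, skey)
    hit <- pos > 0L & skey[pmax(pos, 1L)] == target
    nb[hit, j] <- o[pos[hit]]
  }
  nb
}

#' Density-based clustering of voxels on the integer lattice
#'
#' A single-pass DBSCAN specialised to voxel coordinates. A voxel is a core
#' point when its `epsilon`-neighbourhood (including itself) holds at least
#' `min_pts` voxels; clusters grow from core voxels by breadth-first queue
#' expansion over the neighbourhood graph; voxels reachable from no core
#' point are labeled noise (`cluster_id` 0). Under the default parameters
#' every non-isolated voxel is core and the labeling equals the connected
#' components of the `<= sqrt(2)`-adjacency graph.
#'
#' Cluster IDs are canonical — numbered by decreasing size with ties broken
#' by the smallest member coordinate in x-fastest scan order — so the
#' labeling is identical (not merely isomorphic) across permutations of the
#' input rows.
#'
#' @param universe Integer matrix (n x 3) of distinct voxel coordinates (a
#'   [subject_matrix()] `coords` slot, typically).
#' @param params A [dbscan_params()].
#' @return An object of class `cluster_labeling`: `coords` (as given),
#'   `cluster_id` (integer per voxel, 0 = noise), `sizes` (named vector,
#'   cluster ID -> voxel count).
#' @export
grid_dbscan <- function(universe, params = dbscan_params()) {
  coords <- rbind_coords(universe)
  storage.mode(coords) <- "integer"
  if (anyDuplicated(coords)) stop("'universe' must not contain duplicates")
  n <- nrow(coords)
  if (n == 0L)
    return(new_labeling(coords, integer(0)))
  nb <- neighbor_index(coords, params$epsilon)
  n_neigh <- rowSums(!is.na(nb))
  core <- (n_neigh + 1L) >= params$min_pts
  lab <- integer(n)                    # 0 = unlabeled/noise
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cur <- cur + 1L
    lab[i] <- cur
    frontier <- i
    while (length(frontier)) {
      ## expand only through core members of the frontier
      nxt <- nb[frontier[core[frontier]], , drop = FALSE]
      nxt <- unique(nxt[!is.na(nxt)])
      nxt <- nxt[lab[nxt] == 0L]
      lab[nxt] <- cur
      frontier <- nxt
    }
  }
  new_labeling(coords, canonical_ids(lab, coords))
}

## Renumber positive labels: decreasing size, ties by smallest member key
## in x-fastest scan order.  Noise (0) is preserved.
canonical_ids <- function(lab, coords) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  lo <- apply(coords, 2, min)
  span <- apply(coords, 2, max) - lo + 1L
  key <- vox_key(sweep(coords, 2, lo, "-"), span)
  sizes <- tabulate(lab, nbins = max(ids))[ids]
  minkey <- vapply(ids, function(id) min(key[lab == id]), numeric(1))
  o <- order(-sizes, minkey)
  remap <- integer(max(ids))
  remap[ids[o]] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

new_labeling <- function(coords, cluster_id) {
  sizes <- if (length(cluster_id)) tabulate(cluster_id) else integer(0)
  names(sizes) <- seq_along(sizes)
  structure(list(coords = coords, cluster_id = as.integer(cluster_id),
                 sizes = sizes),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("<cluster_labeling> %d voxels, %d cluster(s), %d noise\n",
              nrow(x$coords), length(x$sizes), sum(x$cluster_id == 0L)))
  invisible(x)
}

#' Drop noise voxels and clusters below a size threshold
#'
#' Removes all noise voxels and every cluster with fewer than
#' `min_cluster_size` members, then renumbers the survivors canonically
#' (decreasing size, ties by smallest member coordinate). An empty result is
#' allowed and signalled through the `retained` element.
#'
#' @param labeling A [grid_dbscan()] labeling.
#' @param min_cluster_size Integer retention threshold.
#' @return List with `retained` (indices into the labeling's rows that
#'   survive) and `labeling` (the re-labeled survivors).
#' @export
size_filter <- function(labeling, min_cluster_size = 20L) {
  keep_ids <- as.integer(names(labeling$sizes))[labeling$sizes >= min_cluster_size]
  retained <- which(labeling$cluster_id %in% keep_ids)
  co <- labeling$coords[retained, , drop = FALSE]
  lab <- labeling$cluster_id[retained]
  if (length(lab)) lab <- canonical_ids(lab, co)
  list(retained = retained, labeling = new_labeling(co, lab))
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the minimum size a spatially connected cluster of
#' suprathreshold voxels must reach before its occurrence anywhere in the
#' mask is unlikely under pure noise (family-wise level `alpha`). Each
#' iteration draws white Gaussian noise on the grid, smooths it to
#' `smooth_fwhm_vox` FWHM (per-voxel variance-normalized, so the field is
#' exactly unit variance), keeps the mask-interior voxels exceeding the
#' two-sided `voxel_p` threshold, and records the largest connected cluster
#' under the same `<= sqrt(2)` lattice adjacency the pipeline uses. The
#' returned `k` is the smallest integer such that the fraction of iterations
#' whose maximum cluster reaches `k` is at most `alpha`.
#'
#' @param geometry A [vox_geometry()].
#' @param mask A [brain_mask()] on that geometry.
#' @param smooth_fwhm_vox Noise smoothness, FWHM in voxels (0 = independent
#'   voxels).
#' @param voxel_p Two-sided per-voxel probability threshold, in (0, 1).
#' @param alpha Family-wise cluster-level rate, in (0, 1); must be
#'   resolvable, i.e. `alpha >= 1/n_iter`.
#' @param n_iter Number of noise simulations (>= 100).
#' @param seed Integer RNG seed.
#' @return Integer cluster-extent threshold (voxels), with the simulated
#'   per-iteration maxima attached as attribute `"max_sizes"`.
#' @export
estimate_cluster_threshold <- function(geometry, mask, smooth_fwhm_vox,
                                       voxel_p = 0.002, alpha = 0.01,
                                       n_iter = 1000L, seed = 1L) {
  if (voxel_p <= 0 || voxel_p >= 1) stop("'voxel_p' must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (n_iter < 100L) stop("'n_iter' must be >= 100")
  if (alpha < 1 / n_iter)
    stop("'n_iter' too small to resolve 'alpha' (need alpha >= 1/n_iter)")
  if (!geometry_equal(geometry, mask$geometry))
    stop("mask geometry does not match 'geometry'")
  shape <- geometry$shape
  zthr <- stats::qnorm(1 - voxel_p / 2)
  inside_idx <- which(mask$inside)
  smoother <- if (smooth_fwhm_vox > 0) {
    k <- gauss_kernel(smooth_fwhm_vox)
    S <- lapply(shape, conv_band, kernel = k)
    S2 <- lapply(shape, conv_band, kernel = k^2)
    sd_field <- sqrt(conv_separable(array(1, shape), S2))
    function(v) conv_separable(v, S) / sd_field
  } else identity
  max_sizes <- with_seed(seed, {
    ms <- integer(n_iter)
    for (it in seq_len(n_iter)) {
      z <- smoother(array(stats::rnorm(prod(shape)), shape))
      sup <- inside_idx[abs(z[inside_idx]) >= zthr]
      ms[it] <- if (length(sup)) {
        co <- arrayInd(sup, shape) - 1L
        labx <- grid_dbscan(co, dbscan_params())
        max(c(labx$sizes, 1L))         # isolated voxels count as extent 1
      } else 0L
    }
    ms
  })
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  structure(k, max_sizes = max_sizes)
}
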