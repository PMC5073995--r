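test_that("the sqrt(2) neighbourhood is faces plus edges, never corners", {
  u <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 1, 1))
  nb <- voxel_neighbors(c(0, 0, 0), u)
  expect_equal(nrow(nb), 1L)
  expect_equal(nb[1, ], c(1, 1, 0), ignore_attr = TRUE)  # edge neighbour
  # centre of a full 3x3x3 block: 6 faces + 12 edges = 18 neighbours
  full <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  expect_equal(nrow(voxel_neighbors(c(1, 1, 1), full)), 18L)
  # brute-force: exactly the offsets at squared distance 1 or 2
  offs <- voxrfe:::lattice_offsets(sqrt(2))
  expect_equal(sort(rowSums(offs^2)), rep(c(1, 2), c(6, 12)))
})

test_that("isolated voxels are noise; an edge-sharing pair is a cluster", {
  l1 <- grid_dbscan(matrix(c(0, 0, 0), 1, 3))
  expect_equal(l1$cluster_id, 0L)
  l2 <- grid_dbscan(rbind(c(0, 0, 0), c(1, 1, 0)))
  expect_equal(l2$cluster_id, c(1L, 1L))
  expect_equal(unname(l2$sizes), 2L)
  l3 <- grid_dbscan(rbind(c(0, 0, 0), c(1, 1, 1)))  # corners do not connect
  expect_equal(l3$cluster_id, c(0L, 0L))
})

test_that("grid_dbscan equals brute-force connected components on random universes", {
  set.seed(2024)
  for (rep in 1:200) {
    n <- sample(c(5:50, 300, 600, 1000), 1)
    box <- sample(4:10, 1)
    co <- unique(cbind(sample(0:box, n, TRUE), sample(0:box, n, TRUE),
                       sample(0:box, n, TRUE)))
    lab <- grid_dbscan(co)
    oracle <- cc_oracle(co)
    # noise = singleton components under default params
    oracle_sizes <- table(oracle)
    oracle_lab <- ifelse(oracle_sizes[as.character(oracle)] == 1, 0L, oracle)
    expect_true(same_partition(lab$cluster_id, as.integer(oracle_lab)))
    # partition invariant: cluster sizes + noise = universe
    expect_equal(sum(lab$sizes) + sum(lab$cluster_id == 0), nrow(co))
  }
})

test_that("the labeling is bit-stable under input permutation", {
  set.seed(5)
  co <- unique(cbind(sample(0:8, 120, TRUE), sample(0:8, 120, TRUE),
                     sample(0:8, 120, TRUE)))
  lab <- grid_dbscan(co)
  o <- sample(nrow(co))
  lab_p <- grid_dbscan(co[o, ])
  # canonical IDs: voxel-for-voxel identical labels after reordering back
  expect_identical(lab_p$cluster_id[order(o)], lab$cluster_id)
  expect_identical(lab_p$sizes, lab$sizes)
})

test_that("the size filter drops small clusters and renumbers canonically", {
  # build three separated components of sizes 25, 19, 3 plus one singleton
  line <- function(n, y, z) cbind(0:(n - 1), y, z)
  co <- rbind(line(25, 0, 0), line(19, 5, 0), line(3, 10, 0),
              c(0, 15, 0))
  lab <- grid_dbscan(co)
  expect_equal(sort(unname(lab$sizes), decreasing = TRUE), c(25, 19, 3))
  kept <- size_filter(lab, 20)
  expect_equal(length(kept$retained), 25L)
  expect_equal(unname(kept$labeling$sizes), 25L)
  # threshold 1 drops only noise
  all_k <- size_filter(lab, 1)
  expect_equal(length(all_k$retained), 25 + 19 + 3)
  # empty result is allowed
  none <- size_filter(lab, 100)
  expect_length(none$retained, 0)
  # renumbering: descending size, then smallest member coordinate
  expect_equal(unname(all_k$labeling$sizes[1]), 25L)
})

test_that("cluster-extent threshold behaves at the edges and matches an oracle", {
  g <- vox_geometry(c(12, 12, 12))
  mask <- make_mask(c(12, 12, 12), "full_box", g)
  # threshold so strict that no voxel ever survives -> returns 1
  expect_equal(as.integer(estimate_cluster_threshold(
    g, mask, smooth_fwhm_vox = 0, voxel_p = 1e-12, alpha = 0.05,
    n_iter = 100, seed = 1)), 1L)
  expect_error(estimate_cluster_threshold(g, mask, 0, 0.01, alpha = 0.001,
                                          n_iter = 100, seed = 1),
               "n_iter")

  # independent-voxel case against a brute-force oracle at 10x iterations
  g20 <- vox_geometry(c(20, 20, 20))
  mask20 <- make_mask(c(20, 20, 20), "full_box", g20)
  k_pkg <- as.integer(estimate_cluster_threshold(
    g20, mask20, smooth_fwhm_vox = 0, voxel_p = 0.002, alpha = 0.01,
    n_iter = 200, seed = 7))
  set.seed(99)
  n_iter <- 2000
  mx <- integer(n_iter)
  zthr <- qnorm(1 - 0.002 / 2)
  for (it in seq_len(n_iter)) {
    z <- array(rnorm(8000), c(20, 20, 20))
    sup <- which(abs(z) >= zthr)
    mx[it] <- if (length(sup)) {
      comp <- cc_oracle(arrayInd(sup, c(20, 20, 20)))
      max(table(comp))
    } else 0L
  }
  k_oracle <- 1L
  while (mean(mx >= k_oracle) > 0.01) k_oracle <- k_oracle + 1L
  expect_lte(abs(k_pkg - k_oracle), 1L)

  # monotone: smoothing can only raise the threshold
  k_smooth <- as.integer(estimate_cluster_threshold(
    g20, mask20, smooth_fwhm_vox = 2, voxel_p = 0.002, alpha = 0.01,
    n_iter = 200, seed = 7))
  expect_gte(k_smooth, k_pkg)
})
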