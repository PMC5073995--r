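test_that("masks are deterministic and correctly sized", {
  expect_equal(make_mask(c(4, 4, 4), "full_box")$n_inside, 64L)
  ell <- make_mask(c(10, 12, 8), "ellipsoid")
  expect_lt(ell$n_inside, prod(c(10, 12, 8)))
  expect_gt(ell$n_inside, 0)
  expect_identical(ell$inside, make_mask(c(10, 12, 8), "ellipsoid")$inside)
  expect_error(make_mask(c(3, 8, 8), "ellipsoid"), ">= 4")
})

test_that("planted clusters are disjoint in-mask balls with the right size", {
  # radius-2 lattice ball has 33 voxels (brute-force count)
  expect_equal(nrow(voxrfe:::ball_offsets(2)),
               sum(rowSums(as.matrix(
                 expand.grid(-2:2, -2:2, -2:2))^2) <= 4))
  expect_equal(nrow(voxrfe:::ball_offsets(2)), 33L)

  cfg <- synth_config(shape = c(24, 26, 22), n_effect_clusters = 3,
                      cluster_radius_vox = 2, seed = 4)
  mask <- make_mask(cfg$shape, cfg$mask_kind)
  gt <- plant_clusters(mask, cfg)
  expect_length(gt$clusters, 3)
  for (cl in gt$clusters) {
    expect_equal(nrow(cl), 33L)
    expect_true(all(mask$inside[cl + 1L]))
  }
  expect_equal(nrow(gt$effect_voxels), 99L)          # pairwise disjoint
  expect_equal(anyDuplicated(gt$effect_voxels), 0L)
  # determinism and the empty case
  gt2 <- plant_clusters(mask, cfg)
  expect_identical(gt$effect_voxels, gt2$effect_voxels)
  expect_identical(gt$signs, gt2$signs)
  cfg0 <- synth_config(shape = c(24, 26, 22), n_effect_clusters = 0)
  expect_equal(nrow(plant_clusters(mask, cfg0)$effect_voxels), 0L)
  # impossible placements fail with advice
  cfg_big <- synth_config(shape = c(12, 12, 12), n_effect_clusters = 50,
                          cluster_radius_vox = 3)
  expect_error(plant_clusters(make_mask(c(12, 12, 12), "ellipsoid"), cfg_big),
               "larger mask")
})

test_that("cohort generation is reproducible and respects the model", {
  # degenerate: no effect, no noise -> all subjects identical and constant
  cfg0 <- synth_config(shape = c(10, 10, 8), n_pos = 2, n_ctrl = 2,
                       n_effect_clusters = 0, effect_size = 0,
                       noise_sigma = 0, seed = 3)
  co0 <- generate_cohort(cfg0)
  expect_equal(max(abs(co0$matrix$values - cfg0$baseline_mean)), 0)

  # bit-identical under the same config
  cfg <- synth_config(shape = c(14, 14, 12), n_pos = 4, n_ctrl = 4, seed = 9,
                      n_effect_clusters = 1, cluster_radius_vox = 2)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_true(all(is.finite(a$matrix$values)))
  expect_s3_class(a$matrix$labels, "factor")
  expect_equal(as.vector(table(a$matrix$labels)), c(4, 4))

  # strong effect, small noise: group mean difference has the planted sign
  cfg_s <- synth_config(shape = c(20, 22, 18), n_pos = 8, n_ctrl = 8,
                        n_effect_clusters = 2, cluster_radius_vox = 2,
                        effect_size = 0.3, noise_sigma = 1, seed = 12)
  co <- generate_cohort(cfg_s)
  m <- co$matrix
  pos <- m$labels == "positive"
  ckey <- do.call(paste, as.data.frame(m$coords))
  for (i in seq_along(co$truth$clusters)) {
    cols <- match(do.call(paste, as.data.frame(co$truth$clusters[[i]])), ckey)
    d <- mean(m$values[pos, cols]) - mean(m$values[!pos, cols])
    expect_equal(sign(d), co$truth$signs[i])
  }
})

test_that("null cohorts reject at the nominal voxelwise rate", {
  cfg <- synth_config(shape = c(20, 22, 18), n_pos = 20, n_ctrl = 20,
                      effect_size = 0, seed = 31)
  co <- generate_cohort(cfg)
  v <- co$matrix$values
  pos <- co$matrix$labels == "positive"
  n1 <- sum(pos); n2 <- sum(!pos)
  m1 <- colMeans(v[pos, ]); m2 <- colMeans(v[!pos, ])
  s1 <- apply(v[pos, ], 2, var); s2 <- apply(v[!pos, ], 2, var)
  tstat <- (m1 - m2) / sqrt(s1 / n1 + s2 / n2)
  df <- (s1 / n1 + s2 / n2)^2 /
    ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  rate <- mean(p < 0.05)
  # voxels are spatially correlated, so allow a generous band around 5%
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
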