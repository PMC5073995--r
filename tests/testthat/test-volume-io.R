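test_that("cohorts load with fixed x-fastest column order and strict checks", {
  dir <- withr::local_tempdir()
  geom <- vox_geometry(c(2, 2, 2), c(2, 2, 2))
  inside <- array(FALSE, c(2, 2, 2))
  inside[c(1, 2, 3, 5, 8)] <- TRUE          # 5 interior voxels
  mask <- brain_mask(inside, geom)
  write_mask(mask, file.path(dir, "mask.nii.gz"))
  vols <- file.path(dir, c("a.nii.gz", "b.nii.gz"))
  arr1 <- array(1:8, c(2, 2, 2)); arr2 <- array(8:1, c(2, 2, 2))
  voxrfe:::write_nifti_volume(arr1, geom, vols[1])
  voxrfe:::write_nifti_volume(arr2, geom, vols[2])
  tab <- data.frame(subject_id = c("s1", "s2"), path = vols,
                    label = c("ctrl", "pos"))
  m <- load_cohort(tab, file.path(dir, "mask.nii.gz"))
  expect_equal(dim(m$values), c(2L, 5L))
  expect_equal(nrow(m$coords), 5L)
  # x-fastest enumeration of interior voxels
  expect_equal(m$coords[, 1], c(0L, 1L, 0L, 0L, 1L), ignore_attr = TRUE)
  expect_equal(m$values[1, ], c(1, 2, 3, 5, 8), ignore_attr = TRUE)
  # reload is bit-identical
  m2 <- load_cohort(tab, file.path(dir, "mask.nii.gz"))
  expect_identical(m$values, m2$values)
  expect_identical(m$coords, m2$coords)

  # geometry mismatch names the offending file
  bad <- file.path(dir, "bad.nii.gz")
  voxrfe:::write_nifti_volume(array(1, c(3, 2, 2)),
                              vox_geometry(c(3, 2, 2), c(2, 2, 2)), bad)
  tab_bad <- tab; tab_bad$path[2] <- bad
  expect_error(load_cohort(tab_bad, file.path(dir, "mask.nii.gz")), "bad.nii")

  # NaN inside the mask is rejected
  arr_nan <- arr1; arr_nan[1] <- NaN
  voxrfe:::write_nifti_volume(arr_nan, geom, file.path(dir, "nan.nii.gz"))
  tab_nan <- tab; tab_nan$path[1] <- file.path(dir, "nan.nii.gz")
  expect_error(load_cohort(tab_nan, file.path(dir, "mask.nii.gz")),
               "non-finite")

  # duplicate and missing labels are rejected
  tab_dup <- rbind(tab, tab[1, ])
  expect_error(load_cohort(tab_dup, file.path(dir, "mask.nii.gz")),
               "duplicate")
  tab_na <- tab; tab_na$label[1] <- NA
  expect_error(load_cohort(tab_na, file.path(dir, "mask.nii.gz")), "label")
})

test_that("whole-brain normalization yields unit-mean rows and is idempotent", {
  m <- make_sm(matrix(5, 2, 4))
  expect_equal(whole_brain_normalize(m)$values, matrix(1, 2, 4))
  m2 <- make_sm(matrix(c(2, 4), 1, 2), labels = "a")
  expect_equal(whole_brain_normalize(m2)$values[1, ], c(2 / 3, 4 / 3))
  set.seed(42)
  m3 <- make_sm(matrix(rexp(30) + 0.1, 3, 10))
  n1 <- whole_brain_normalize(m3)
  expect_true(all(abs(rowMeans(n1$values) - 1) < 1e-12))
  n2 <- whole_brain_normalize(n1)
  expect_equal(n1$values, n2$values, tolerance = 1e-12)
  m_bad <- make_sm(matrix(c(-2, -4, 1, 1), 2, 2))
  expect_error(whole_brain_normalize(m_bad), "nonpositive")
})

test_that("min-max scaling is fit on train only and maps extremes to +-1", {
  s <- minmax_scale(matrix(c(10, 20), 2, 1), matrix(c(15, 25), 2, 1))
  expect_equal(s$train[, 1], c(-1, 1))
  expect_equal(s$test[, 1], c(0, 2))        # midpoint 0; no clipping
  # constant training column maps everything to 0
  s2 <- minmax_scale(matrix(7, 3, 1), matrix(c(7, 9), 2, 1))
  expect_equal(s2$train[, 1], c(0, 0, 0))
  expect_equal(s2$test[, 1], c(0, 0))
  # property: on train == test every column's extremes hit exactly -1, +1
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(rnorm(60), 6, 10)
    sc <- minmax_scale(x, x)
    expect_equal(apply(sc$train, 2, min), rep(-1, 10), ignore_attr = TRUE)
    expect_equal(apply(sc$train, 2, max), rep(1, 10), ignore_attr = TRUE)
    expect_identical(sc$train, sc$test)
  }
})

test_that("cluster maps round-trip through NIfTI", {
  dir <- withr::local_tempdir()
  geom <- vox_geometry(c(6, 5, 4), c(2, 2, 2))
  # empty labeling -> all zero volume
  empty <- grid_dbscan(matrix(integer(0), 0, 3))
  p0 <- file.path(dir, "empty.nii.gz")
  write_cluster_map(empty, geom, p0)
  expect_true(all(as.array(RNifti::readNifti(p0)) == 0))
  # random labeling round-trips exactly
  set.seed(11)
  co <- unique(cbind(sample(0:5, 40, TRUE), sample(0:4, 40, TRUE),
                     sample(0:3, 40, TRUE)))
  lab <- grid_dbscan(co)
  p1 <- file.path(dir, "lab.nii.gz")
  write_cluster_map(lab, geom, p1)
  arr <- as.array(RNifti::readNifti(p1))
  expect_equal(sum(arr != 0), sum(lab$cluster_id != 0))
  expect_equal(arr[lab$coords + 1L], as.numeric(lab$cluster_id))
  # out-of-bounds coordinates are a hard error
  expect_error(write_cluster_map(lab, vox_geometry(c(2, 2, 2)), p1),
               "outside")
})
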