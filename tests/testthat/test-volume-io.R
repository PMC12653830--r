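test_that("volumes round-trip through NIfTI with slice-axis inference", {
  arr <- array(runif(64 * 64 * 20, 0, 1000), dim = c(64, 64, 20))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 3)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  vol <- read_volume(path, patient_id = "p1")
  expect_equal(dim(vol$voxels), c(64L, 64L, 20L))
  expect_equal(vol$slice_axis, 3L)
  expect_equal(dim(vol$voxels)[vol$slice_axis], 20L)
  expect_equal(read_volume(path, slice_axis = 1)$slice_axis, 1L)
})

test_that("invalid volumes are rejected", {
  arr <- array(1, dim = c(8, 8, 4))
  arr[1, 1, 1] <- NaN
  expect_error(qc_volume(arr), "non-finite")
  path4d <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(8, 8, 4, 3))), path4d)
  expect_error(read_volume(path4d), "post-contrast")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("z-score normalization standardizes the whole slice", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  z <- zscore_normalize(m)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)

  m2 <- matrix(c(0, 0, 0, 10), 2, 2)
  z2 <- zscore_normalize(m2)
  expect_equal(attr(z2, "zscore_mean"), 2.5)
  expect_equal(attr(z2, "zscore_sd"), 4.3301, tolerance = 1e-4)
  expect_equal(sort(unique(round(as.vector(z2), 4))), c(-0.5774, 1.7321))

  expect_error(zscore_normalize(matrix(5, 3, 3)), "zero-variance")
})

test_that("z-score normalization is idempotent", {
  set.seed(7)
  m <- matrix(rnorm(400, 10, 3), 20, 20)
  z1 <- zscore_normalize(m)
  z2 <- zscore_normalize(unclass(z1))
  expect_lt(max(abs(z2 - z1)), 1e-9)
})

test_that("twelve-slice sampling distributes 3/6/3 across thirds", {
  idx <- twelve_slice_indices(60)
  expect_length(idx, 12)
  expect_equal(idx, sort(unique(idx)))
  expect_equal(sum(idx >= 20 & idx < 40), 6)  # middle third
  expect_equal(sum(idx < 20), 3)
  expect_equal(sum(idx >= 40), 3)

  expect_equal(twelve_slice_indices(12), 0:11)  # pigeonhole at minimum Z
  expect_error(twelve_slice_indices(11), "insufficient")
})

test_that("twelve-slice sampling yields 12 unique in-range indices for all Z", {
  for (Z in c(12:30, seq(35, 400, by = 15))) {
    idx <- twelve_slice_indices(Z)
    expect_length(idx, 12)
    expect_equal(anyDuplicated(idx), 0)
    expect_true(all(idx >= 0 & idx < Z))
    expect_false(is.unsorted(idx))
  }
})

test_that("middle slice uses the floor convention and stays central", {
  expect_equal(middle_slice_index(61), 30L)
  expect_equal(middle_slice_index(60), 30L)
  expect_equal(middle_slice_index(1), 0L)
  for (Z in 3:120) {
    i <- middle_slice_index(Z)
    expect_gte(i, floor(Z / 3))
    expect_lt(i, ceiling(2 * Z / 3))
  }
})

test_that("slice sampling returns tagged qc_slice objects", {
  vol <- qc_volume(array(runif(16 * 16 * 24), dim = c(16, 16, 24)),
                   slice_axis = 3, patient_id = "px")
  sl <- sample_slices(vol, "twelve_slice")
  expect_length(sl, 12)
  expect_true(all(vapply(sl, function(s) s$scenario, "") == "twelve_slice"))
  expect_equal(sample_slices(vol, "middle_slice")[[1]]$slice_index, 12L)
})

test_that("manifest validation enforces schema and labels", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = c("a", "b"), volume_path = c("x", "y"),
                       label = c(0L, 1L)), path, row.names = FALSE)
  m <- read_manifest(path)
  expect_equal(nrow(m), 2)
  write.csv(data.frame(patient_id = c("a", "a"), volume_path = c("x", "y"),
                       label = c(0L, 1L)), path, row.names = FALSE)
  expect_error(read_manifest(path), "duplicate")
  write.csv(data.frame(patient_id = c("a", "b"), volume_path = c("x", "y"),
                       label = c(0L, 2L)), path, row.names = FALSE)
  expect_error(read_manifest(path), "labels")
})
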