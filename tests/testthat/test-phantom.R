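test_that("phantom generation is deterministic per seed", {
  v1 <- generate_phantom(phantom_spec(seed = 17))
  v2 <- generate_phantom(phantom_spec(seed = 17))
  expect_identical(v1$voxels, v2$voxels)
  v3 <- generate_phantom(phantom_spec(seed = 18))
  expect_false(identical(v1$voxels, v3$voxels))
})

test_that("cohorts are balanced, reproducible and labeled by severity", {
  c1 <- generate_cohort(11, seed = 9, shape = c(32L, 32L, 12L))
  expect_equal(nrow(c1$manifest), 22)
  expect_equal(sum(c1$manifest$label == 1), 11)
  c2 <- generate_cohort(11, seed = 9, shape = c(32L, 32L, 12L))
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$volumes[[5]]$voxels, c2$volumes[[5]]$voxels)
  for (v in c1$volumes) {
    sp <- attr(v, "spec")
    expect_equal(sp$degradation$label,
                 c1$manifest$label[c1$manifest$patient_id == v$patient_id])
    expect_equal(sp$degradation$label,
                 as.integer(sp$degradation$severity >= 1))
  }
})

test_that("cohort writing produces NIfTI volumes and a readable manifest", {
  dir <- file.path(tempdir(), "cohort_test")
  co <- generate_cohort(2, dir = dir, seed = 4, shape = c(24L, 24L, 12L))
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 4)
  vol <- read_volume(m$volume_path[1], patient_id = m$patient_id[1])
  expect_equal(dim(vol$voxels), c(24L, 24L, 12L))
  expect_equal(vol$slice_axis, 3L)  # through-plane spacing is largest
  spec <- jsonlite::read_json(file.path(dir, "P001.json"))
  expect_equal(spec$label, 0L)
  unlink(dir, recursive = TRUE)
})

test_that("an all-zero degradation is the identity", {
  set.seed(1)
  arr <- array(runif(16 * 16 * 4, 0, 100), dim = c(16, 16, 4))
  out <- degrade_volume(arr, degradation_spec())
  expect_equal(max(abs(out - arr)), 0)
})

test_that("doubling noise sigma doubles the added-component SD", {
  arr <- array(500, dim = c(64, 64, 2))
  ratios <- vapply(1:20, function(seed) {
    set.seed(seed)
    a <- degrade_volume(arr, degradation_spec(noise_sigma = 20)) - arr
    set.seed(seed + 100)
    b <- degrade_volume(arr, degradation_spec(noise_sigma = 40)) - arr
    sd(b) / sd(a)
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("blur reduces anatomy total variation; zebra and ghost modulate", {
  vol <- generate_phantom(phantom_spec(seed = 23))
  sl <- vol$voxels[, , 10]
  blurred <- degrade_volume(vol$voxels, degradation_spec(blur_sigma = 2))
  expect_lt(total_variation(blurred[, , 10]), total_variation(sl))
  zebra <- degrade_volume(vol$voxels,
                          degradation_spec(zebra_amplitude = 0.3,
                                           zebra_period = 8))
  expect_gt(total_variation(zebra[, , 10]), total_variation(sl))
  ghost <- degrade_volume(vol$voxels,
                          degradation_spec(ghost_shift = 12,
                                           ghost_amplitude = 0.3))
  expect_gt(mean(ghost[, , 10]), mean(sl))  # attenuated copy adds signal
})

test_that("degraded volumes have noisier corners than clean ones", {
  hits <- 0
  for (seed in 1:50) {
    clean <- generate_phantom(phantom_spec(
      seed = seed, degradation = degradation_spec()))
    noisy <- generate_phantom(phantom_spec(
      seed = seed, degradation = degradation_spec(noise_sigma = 90)))
    cv_of <- function(v) {
      sq <- corner_squares(get_slice(v, 11)$pixels)
      mean(vapply(sq, function(s) {
        px <- get_slice(v, 11)$pixels
        var(as.vector(px[(s$row_range[1] + 1):s$row_range[2],
                         (s$col_range[1] + 1):s$col_range[2]]))
      }, numeric(1)))
    }
    if (cv_of(noisy) > cv_of(clean)) hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("rician noise produces a non-negative magnitude image", {
  arr <- array(10, dim = c(16, 16, 2))
  set.seed(2)
  out <- degrade_volume(arr, degradation_spec(noise_sigma = 30,
                                              rician = TRUE))
  expect_true(all(out >= 0))
  expect_gt(mean(out), 10)  # Rician bias lifts the mean at low SNR
})
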