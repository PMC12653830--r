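dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

test_that("texture matrices match brute-force enumeration exactly", {
  for (seed in 1:12) {
    lv <- random_level_image(seed, max_side = 8L, ng = 4L)
    ng <- 4L
    for (d in dirs) {
      expect_identical(cpp_glcm(lv, ng, d[1], d[2]),
                       naive_glcm(lv, ng, d[1], d[2]))
      expect_identical(cpp_glrlm(lv, ng, d[1], d[2]),
                       naive_glrlm(lv, ng, d[1], d[2]))
    }
    if (any(lv > 0)) {
      P <- cpp_glszm(lv, ng)
      Q <- naive_glszm(lv, ng)
      expect_identical(P[, seq_len(ncol(Q)), drop = FALSE], Q)
      if (ncol(P) > ncol(Q)) expect_true(all(P[, -seq_len(ncol(Q))] == 0))
    }
    for (alpha in 0:1)
      expect_identical(cpp_gldm(lv, ng, alpha), naive_gldm(lv, ng, alpha))
    expect_equal(cpp_ngtdm(lv, ng), naive_ngtdm(lv, ng), tolerance = 1e-12)
  }
})

test_that("checkerboard GLCM direction-averaged contrast is one half", {
  lv <- 1L + outer(1:4, 1:4, "+") %% 2L  # two-level checkerboard
  attr(lv, "ng") <- 2L
  f <- glcm_features(lv)
  expect_equal(unname(f["Contrast"]), 0.5)
  # horizontal and vertical contrasts are 1, both diagonals 0
  Ph <- cpp_glcm(lv, 2L, 0L, 1L)
  expect_equal(sum(Ph * (outer(1:2, 1:2, "-"))^2) / sum(Ph), 1)
  Pd <- cpp_glcm(lv, 2L, 1L, 1L)
  expect_equal(sum(Pd * (outer(1:2, 1:2, "-"))^2) / sum(Pd), 0)
})

test_that("horizontal runs of [1,1,2,2] give two length-2 runs", {
  lv <- matrix(c(1L, 1L, 2L, 2L), 1, 4)
  P <- cpp_glrlm(lv, 2L, 0L, 1L)
  expect_equal(P[1, 2], 1)
  expect_equal(P[2, 2], 1)
  expect_equal(sum(P), 2)
  # run-length non-uniformity by hand: (0^2 + 2^2) / 2 = 2
  expect_equal(sum(colSums(P)^2) / sum(P), 2)
})

test_that("constant regions take their analytic degenerate values", {
  lv <- matrix(1L, 6, 6)
  attr(lv, "ng") <- 1L
  g <- glcm_features(lv)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["Correlation"]), 1)  # convention for sigma = 0
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_equal(unname(g["JointEnergy"]), 1)
  expect_equal(unname(g["MaximumProbability"]), 1)

  z <- glszm_features(lv)
  expect_equal(unname(z["ZoneEntropy"]), 0)  # a single 36-pixel zone
  expect_equal(unname(z["ZonePercentage"]), 1 / 36)
  expect_equal(unname(z["LargeAreaEmphasis"]), 36^2)

  n <- ngtdm_features(lv)
  expect_equal(unname(n["Complexity"]), 0)
  expect_equal(unname(n["Contrast"]), 0)
  expect_equal(unname(n["Coarseness"]), 1e6)  # capped 1/0

  r <- glrlm_features(lv)
  expect_equal(unname(r["LowGrayLevelRunEmphasis"]), 1)  # single level
  d <- gldm_features(lv)
  expect_equal(unname(d["GrayLevelNonUniformity"]), 36)  # all one level
})

test_that("feature vectors have the configured class sizes", {
  lv <- random_level_image(99, max_side = 8L, ng = 3L, with_mask = FALSE)
  attr(lv, "ng") <- 3L
  expect_length(glcm_features(lv), 22)
  expect_length(glrlm_features(lv), 16)
  expect_length(glszm_features(lv), 16)
  expect_length(gldm_features(lv), 14)
  expect_length(ngtdm_features(lv), 5)
})

test_that("texture features are shift-invariant, first-order mean shifts", {
  set.seed(11)
  px <- matrix(runif(24 * 24, 0, 300), 24, 24)
  mask <- matrix(TRUE, 24, 24)
  w <- 10
  lv1 <- dceqc:::level_image(px, mask, w)
  lv2 <- dceqc:::level_image(px + 123.4, mask, w)
  expect_identical(unclass(lv1), unclass(lv2))  # FBS is min-referenced
  f1 <- firstorder_features(px[mask])
  f2 <- firstorder_features(px[mask] + 123.4)
  expect_equal(unname(f2["Mean"] - f1["Mean"]), 123.4)
  expect_equal(unname(f2["Variance"]), unname(f1["Variance"]))
})
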