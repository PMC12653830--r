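logit_model <- function(w, b = 0) {
  function(x) as.numeric(1 / (1 + exp(-(as.matrix(x) %*% w + b))))
}

test_that("single-feature attributions carry the sign of w * (x - mean)", {
  set.seed(3)
  bg <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "f"))
  x <- matrix(c(2, -2), 2, 1, dimnames = list(NULL, "f"))
  att <- kernel_shap(logit_model(1.5), x, bg)
  expect_gt(att$phi[1, 1], 0)
  expect_lt(att$phi[2, 1], 0)
  att2 <- kernel_shap(logit_model(-1.5), x, bg)
  expect_lt(att2$phi[1, 1], 0)
})

test_that("local accuracy holds exactly on every explained sample", {
  set.seed(4)
  m <- 6
  w <- rnorm(m)
  bg <- matrix(rnorm(80 * m), 80, m, dimnames = list(NULL, paste0("f", 1:m)))
  x <- matrix(rnorm(10 * m), 10, m, dimnames = list(NULL, paste0("f", 1:m)))
  att <- kernel_shap(logit_model(w), x, bg, seed = 1)
  resid <- att$base_value + rowSums(att$phi) - att$model_output
  expect_lt(max(abs(resid)), 1e-3)
})

test_that("constant features receive zero attribution", {
  set.seed(5)
  bg <- cbind(f1 = rnorm(40), f2 = 1)
  x <- cbind(f1 = c(1.5, -0.5), f2 = 1)
  att <- kernel_shap(logit_model(c(2, 3)), x, bg, seed = 1)
  expect_lt(max(abs(att$phi[, "f2"])), 1e-10)
})

test_that("duplicated features share the single feature's attribution", {
  set.seed(6)
  z <- rnorm(60)
  bg <- cbind(a = z, b = z, c = rnorm(60))
  xz <- c(2, -1)
  x <- cbind(a = xz, b = xz, c = c(0.3, -0.2))
  # model uses the duplicates with equal weight; their total contribution
  # must match a single feature carrying the combined weight
  att_dup <- kernel_shap(logit_model(c(1, 1, 0.5)), x, bg, seed = 1)
  att_one <- kernel_shap(logit_model(c(2, 0.5)),
                         x[, c("a", "c")], bg[, c("a", "c")], seed = 1)
  expect_equal(att_dup$phi[, "a"] + att_dup$phi[, "b"],
               att_one$phi[, "a"], tolerance = 0.05)
  # symmetry axiom: identical features receive identical attributions
  expect_equal(att_dup$phi[, "a"], att_dup$phi[, "b"], tolerance = 1e-6)
})

test_that("a planted dominant feature tops the summary ranking", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 80; m <- 8
    X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("f", 1:m)))
    w <- c(4, rep(0.3, m - 1))
    y <- as.integer(1 / (1 + exp(-X %*% w)) > 0.5)
    if (length(unique(y)) < 2) next
    fit <- suppressWarnings(glm(y ~ ., data = data.frame(X, y = y),
                                family = binomial()))
    pf <- function(z) as.numeric(predict(fit, newdata = data.frame(z),
                                         type = "response"))
    att <- kernel_shap(pf, X[1:15, ], X, seed = seed)
    if (summary_ranking(att)$feature[1] == "f1") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("ranking covers the selected feature set and is seed-stable", {
  set.seed(9)
  n <- 60; m <- 5
  X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("f", 1:m)))
  w <- c(3, -2, 1, 0.5, 0.1)
  pf <- logit_model(w)
  att1 <- kernel_shap(pf, X[1:12, ], X, seed = 1)
  att2 <- kernel_shap(pf, X[1:12, ], X, seed = 2)
  rk1 <- summary_ranking(att1); rk2 <- summary_ranking(att2)
  expect_equal(nrow(rk1), m)
  expect_setequal(rk1$feature, colnames(X))
  tau <- cor(match(rk1$feature, colnames(X)),
             match(rk2$feature, colnames(X)), method = "kendall")
  expect_gte(tau, 0.6)
})

test_that("background signal surfaces bg-suffixed features in the ranking", {
  # noise-only degradation: the background ROI carries the discriminative
  # signal, so bg-suffixed features must appear among the top attributions
  n <- 8
  vols <- lapply(1:(2 * n), function(i) {
    lab <- as.integer(i > n)
    v <- generate_phantom(phantom_spec(
      shape = c(48L, 48L, 12L),
      degradation = degradation_spec(noise_sigma = if (lab) 110 else 5),
      seed = 4000L + i))
    v$patient_id <- sprintf("N%02d", i)
    v
  })
  co <- list(manifest = data.frame(patient_id = sprintf("N%02d", 1:(2 * n)),
                                   volume_path = NA_character_,
                                   label = rep(c(0L, 1L), each = n)),
             volumes = vols)
  tab <- extract_cohort(co, "middle_slice", "combined")
  rep_ <- run_cv(tab, cv_config(n_folds = 2, seed = 1,
                                classifiers = "logreg"))
  att <- explain_best_fold(rep_$logreg, tab, attr(rep_, "folds"), seed = 1)
  rk <- summary_ranking(att)
  expect_equal(nrow(rk), length(attr(att, "features")))
  expect_true(any(grepl("_bg$", rk$feature)))
})
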