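test_that("patient-stratified folds balance classes and never split patients", {
  manifest <- data.frame(patient_id = sprintf("p%03d", 1:220),
                         label = rep(c(0L, 1L), each = 110))
  folds <- stratified_patient_folds(manifest, 10, seed = 1)
  counts <- table(folds$fold, folds$label)
  expect_true(all(counts == 11))  # 110+110 over 10 folds -> 11+11 each
  expect_equal(anyDuplicated(folds$patient_id), 0)

  # slice-level table: every slice of a patient shares the fold
  tab <- tabular_cohort(3, n_per_class = 12L, slices_per_patient = 4L)
  f2 <- stratified_patient_folds(unique(tab[, c("patient_id", "label")]),
                                 4, seed = 2)
  fmap <- setNames(f2$fold, f2$patient_id)
  per_pat <- tapply(fmap[tab$patient_id], tab$patient_id,
                    function(v) length(unique(v)))
  expect_true(all(per_pat == 1))

  f3 <- stratified_patient_folds(manifest, 10, seed = 99)
  expect_false(identical(folds$fold[order(folds$patient_id)],
                         f3$fold[order(f3$patient_id)]))
  expect_equal(table(f3$fold, f3$label), counts)
  expect_error(stratified_patient_folds(manifest[c(1:12, 111:115), ], 10),
               "at least 10")
})

test_that("confusion-count metrics follow their definitions", {
  truth <- c(rep(1, 10), rep(0, 10))
  prob <- c(rep(0.9, 9), 0.1, rep(0.1, 8), 0.9, 0.9)  # TP9 FN1 TN8 FP2
  m <- dceqc:::classification_metrics(truth, prob)
  expect_equal(unname(m["sensitivity"]), 90)
  expect_equal(unname(m["specificity"]), 80)
  expect_equal(unname(m["accuracy"]), 85)
})

test_that("soft voting averages probabilities with ties to high quality", {
  v <- soft_vote(rep(0.6, 12))
  expect_equal(v$mean_probability, 0.6)
  expect_equal(v$label, 1L)
  v2 <- soft_vote(c(rep(0.9, 6), rep(0.1, 6)))
  expect_equal(v2$mean_probability, 0.5)
  expect_equal(v2$label, 0L)  # exact tie votes high quality
  v3 <- soft_vote(c(0.55, rep(0.45, 11)))
  expect_equal(v3$mean_probability, 0.4583, tolerance = 1e-4)
  expect_equal(v3$label, 0L)
})

test_that("cross-fold aggregation reports mean, population SD and best fold", {
  mk <- function(id, acc, auc) {
    structure(list(fold_id = id, classifier = "x",
                   metrics = c(sensitivity = acc, specificity = acc,
                               accuracy = acc, auc = auc),
                   n_selected = 3), class = "fold_result")
  }
  rep_ <- aggregate_cv(list(mk(1, 80, 90), mk(2, 90, 85)))
  expect_equal(unname(rep_$mean["accuracy"]), 85)
  expect_equal(unname(rep_$sd["accuracy"]), 5)  # population SD across folds
  expect_equal(rep_$best_fold$fold_id, 2)
  # ACC tie broken by AUC, then by the lower fold id
  rep2 <- aggregate_cv(list(mk(1, 85, 80), mk(2, 85, 95), mk(3, 85, 95)))
  expect_equal(rep2$best_fold$fold_id, 2)
  rep3 <- aggregate_cv(list(mk(1, 85, 80), mk(2, 85, 80)))
  expect_equal(rep3$best_fold$fold_id, 1)
  expect_equal(unname(aggregate_cv(list(mk(1, 80, 90),
                                        mk(2, 80, 90)))$sd["accuracy"]), 0)
})

test_that("every classifier scores perfectly on separable features", {
  tab <- tabular_cohort(5, n_per_class = 20L, p = 10L, k = 3L, effect = 6)
  reports <- run_cv(tab, cv_config(n_folds = 4, seed = 2))
  for (id in names(reports)) {
    expect_gte(unname(reports[[id]]$mean["accuracy"]), 95)
    expect_gte(unname(reports[[id]]$mean["auc"]), 99)
  }
})

test_that("label-permuted data scores near chance AUC", {
  aucs <- vapply(1:5, function(seed) {
    tab <- tabular_cohort(seed, n_per_class = 30L, p = 10L, k = 10L,
                          effect = 3)
    set.seed(seed + 500)
    relab <- sample(unique(tab$patient_id))
    newlab <- setNames(rep(c(0L, 1L), 30), relab)  # labels shuffled
    tab$label <- newlab[tab$patient_id]
    r <- run_cv(tab, cv_config(n_folds = 4, seed = seed,
                               classifiers = "logreg",
                               selection = selection_config(top_k = 5)))
    unname(r$logreg$mean["auc"])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 50), 12)
})

test_that("fitting is untouched by test-fold corruption (no leakage)", {
  tab <- tabular_cohort(11, n_per_class = 20L, p = 30L, k = 3L)
  folds <- stratified_patient_folds(unique(tab[, c("patient_id", "label")]),
                                    4, seed = 0)
  fmap <- setNames(folds$fold, folds$patient_id)
  tr <- tab[fmap[tab$patient_id] != 1, ]
  te <- tab[fmap[tab$patient_id] == 1, ]
  te_bad <- te
  fc <- feature_columns(tab)
  te_bad[, fc] <- te_bad[, fc] + matrix(rnorm(nrow(te) * length(fc), sd = 9),
                                        nrow(te))
  te_bad$label <- 1L - te_bad$label
  f1 <- train_and_score(tr, te, "svm_rbf", cv_config(n_folds = 4, seed = 0))
  f2 <- train_and_score(tr, te_bad, "svm_rbf",
                        cv_config(n_folds = 4, seed = 0))
  expect_identical(f1$selector[c("features", "center", "scale")],
                   f2$selector[c("features", "center", "scale")])
  expect_identical(f1$model$model$coefs, f2$model$model$coefs)
  expect_identical(f1$model$model$rho, f2$model$model$rho)
  expect_identical(f1$model$model$SV, f2$model$model$SV)
  expect_false(identical(f1$metrics, f2$metrics))  # predictions did change
})

test_that("soft voting preserves accuracy when slices share a probability", {
  set.seed(21)
  for (i in 1:20) {
    p_true <- runif(1)
    label <- as.integer(p_true > 0.5)
    probs <- rep(p_true, 12)
    expect_equal(soft_vote(probs)$label, label)
  }
})
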