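#' Cross-validation configuration
#'
#' @param n_folds Number of folds (default 10).
#' @param seed Root seed controlling fold assignment and any stochastic
#'   classifier.
#' @param classifiers Subset of `"logreg"`, `"svm_rbf"`, `"knn"`,
#'   `"random_forest"`, `"adaboost"`, `"gaussian_nb"`.
#' @param vote_threshold Soft-voting threshold on the mean class-1
#'   probability (default 0.5; a tie at exactly 0.5 yields high quality).
#' @param selection A [selection_config()].
#' @return List with class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, seed = 0L,
                      classifiers = c("logreg", "svm_rbf", "knn",
                                      "random_forest", "adaboost",
                                      "gaussian_nb"),
                      vote_threshold = 0.5,
                      selection = selection_config()) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (vote_threshold <= 0 || vote_threshold >= 1)
    stop("vote_threshold must lie in (0, 1)")
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 classifiers = classifiers, vote_threshold = vote_threshold,
                 selection = selection),
            class = "cv_config")
}

#' Patient-stratified fold assignment
#'
#' Shuffles patients within each class (seeded) and deals them round-robin
#' into folds, so per-fold class counts differ from perfect balance by at
#' most one patient and all slices of a patient share a fold.
#'
#' @param manifest data.frame with `patient_id` and `label`.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return data.frame `patient_id`, `label`, `fold` (1-based).
#' @export
stratified_patient_folds <- function(manifest, n_folds = 10L, seed = 0L) {
  tab <- unique(manifest[, c("patient_id", "label")])
  for (lab in unique(tab$label)) {
    if (sum(tab$label == lab) < n_folds)
      stop("need at least ", n_folds, " patients per class")
  }
  rng <- local({
    set.seed(seed)
    lapply(split(tab$patient_id, tab$label), sample)
  })
  out <- do.call(rbind, lapply(names(rng), function(lab) {
    ids <- rng[[lab]]
    data.frame(patient_id = ids, label = as.integer(lab),
               fold = rep_len(seq_len(n_folds), length(ids)))
  }))
  rownames(out) <- NULL
  out
}

# --- classifiers -------------------------------------------------------------
# Each fit function returns an object whose predict gives P(class 1) on a
# standardized feature matrix. Hyperparameters beyond those stated by the
# pipeline (SVM gamma, KNN k, forest size, boosting rounds) are library
# defaults, frozen here.

fit_classifier <- function(id, x, y, seed = 0L) {
  y <- factor(y, levels = c(0, 1))
  if (length(unique(y)) < 2) stop("single-class training fold")
  set.seed(seed)
  model <- switch(id,
    logreg = suppressWarnings(glm(y ~ ., data = data.frame(x, y = y),
                                  family = binomial())),
    svm_rbf = e1071::svm(x, y, kernel = "radial", probability = TRUE),
    knn = list(train = x, y = y, k = min(5L, nrow(x))),
    random_forest = randomForest::randomForest(x, y, ntree = 500),
    adaboost = fit_adaboost(x, as.integer(as.character(y)), n_rounds = 50),
    gaussian_nb = e1071::naiveBayes(x, y),
    stop("unknown classifier: ", id))
  structure(list(id = id, model = model, seed = seed), class = "qc_classifier")
}

predict_prob1 <- function(clf, x) {
  x <- as.matrix(x)
  switch(clf$id,
    logreg = suppressWarnings(
      as.numeric(predict(clf$model, newdata = data.frame(x),
                         type = "response"))),
    svm_rbf = {
      pr <- predict(clf$model, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    knn = {
      pred <- class::knn(clf$model$train, x, clf$model$y, k = clf$model$k,
                         prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    random_forest = predict(clf$model, x, type = "prob")[, "1"],
    adaboost = predict_adaboost(clf$model, x),
    gaussian_nb = predict(clf$model, data.frame(x), type = "raw")[, "1"])
}

# Discrete AdaBoost (SAMME) over depth-1 rpart stumps; probability from the
# logistic of the aggregated margin.
fit_adaboost <- function(x, y, n_rounds = 50) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(x, .y = factor(y, levels = c(0, 1)))
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err <= 0) { stumps[[m]] <- fit; alphas[m] <- 10; break }
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- a
    w <- w * exp(a * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {  # no weak learner beats chance: prior model
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

predict_adaboost <- function(model, x) {
  if (length(model$stumps) == 0)
    return(rep(model$prior, nrow(x)))
  df <- data.frame(x)
  Fm <- rep(0, nrow(x))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(predict(model$stumps[[m]], df,
                                            type = "class")))
    Fm <- Fm + model$alphas[m] * ifelse(pred == 1, 1, -1)
  }
  1 / (1 + exp(-2 * Fm / max(sum(model$alphas), 1e-12)))
}

# --- fold training and metrics ----------------------------------------------

#' Soft-vote a patient's slice probabilities
#'
#' @param probs Per-slice class-1 probabilities of one patient.
#' @param threshold Voting threshold (default 0.5).
#' @return List `mean_probability`, `label` (1 iff mean strictly exceeds the
#'   threshold; a tie votes high quality).
#' @export
soft_vote <- function(probs, threshold = 0.5) {
  if (length(probs) == 0) stop("no probabilities to vote on")
  m <- mean(probs)
  list(mean_probability = m, label = as.integer(m > threshold))
}

classification_metrics <- function(truth, prob, threshold = 0.5) {
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
  auc <- if (length(unique(truth)) == 2) {
    as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  } else NA_real_
  c(sensitivity = 100 * safe_div(tp, tp + fn, NA),
    specificity = 100 * safe_div(tn, tn + fp, NA),
    accuracy = 100 * (tp + tn) / length(truth),
    auc = 100 * auc)
}

#' Train on one fold and score the held-out patients
#'
#' Fits the feature selector and the classifier on the training rows only,
#' predicts class-1 probabilities for the test rows, soft-votes them per
#' patient, and computes patient-level sensitivity, specificity, accuracy
#' and AUC (class 1 = low quality = positive).
#'
#' @param train,test Feature data.frames (from [extract_cohort()]) with
#'   `patient_id`, `label` and feature columns.
#' @param classifier_id One of the classifier ids of [cv_config()].
#' @param cfg A [cv_config()].
#' @param fold_id Identifier stored in the result.
#' @return A `fold_result`: list with the four metrics, per-patient voted
#'   probabilities and labels, the fitted selector and classifier.
#' @export
train_and_score <- function(train, test, classifier_id = "svm_rbf",
                            cfg = cv_config(), fold_id = 1L) {
  fc <- feature_columns(train)
  sel <- fit_feature_selector(train[, fc], train$label, cfg$selection)
  xtr <- apply_feature_selector(sel, train[, fc])
  clf <- fit_classifier(classifier_id, xtr, train$label, seed = cfg$seed)
  xte <- apply_feature_selector(sel, test[, fc])
  prob <- predict_prob1(clf, xte)

  by_patient <- split(seq_len(nrow(test)), test$patient_id)
  voted <- t(vapply(by_patient, function(ix) {
    v <- soft_vote(prob[ix], cfg$vote_threshold)
    c(truth = test$label[ix[1]], prob = v$mean_probability,
      label = v$label)
  }, numeric(3)))
  metrics <- classification_metrics(voted[, "truth"], voted[, "prob"],
                                    cfg$vote_threshold)
  structure(list(fold_id = fold_id, classifier = classifier_id,
                 metrics = metrics,
                 patients = data.frame(patient_id = rownames(voted),
                                       truth = voted[, "truth"],
                                       probability = voted[, "prob"],
                                       predicted = voted[, "label"],
                                       row.names = NULL),
                 selector = sel, model = clf,
                 n_selected = length(sel$features)),
            class = "fold_result")
}

#' Aggregate fold results into a CV report
#'
#' @param fold_results List of `fold_result` objects for one classifier.
#' @return A `cv_report`: mean and population SD of each metric (in
#'   percent), the per-fold table, and the best fold (highest accuracy, ties
#'   broken by AUC then by lowest fold id).
#' @export
aggregate_cv <- function(fold_results) {
  M <- t(vapply(fold_results, function(f) f$metrics, numeric(4)))
  mean_ <- colMeans(M, na.rm = TRUE)
  sd_ <- apply(M, 2, function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))  # population SD across folds
  })
  ord <- order(-M[, "accuracy"], -M[, "auc"],
               vapply(fold_results, function(f) f$fold_id, numeric(1)))
  structure(list(mean = mean_, sd = sd_,
                 folds = data.frame(
                   fold_id = vapply(fold_results, function(f) f$fold_id,
                                    numeric(1)),
                   n_selected = vapply(fold_results, function(f)
                     f$n_selected, numeric(1)),
                   M),
                 best_fold = fold_results[[ord[1]]]),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds | best fold %d\n",
              nrow(x$folds), x$best_fold$fold_id))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %6.2f +/- %5.2f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Patient-stratified cross-validation over the classifier zoo
#'
#' @param features Feature table from [extract_cohort()].
#' @param cfg A [cv_config()].
#' @return Named list of `cv_report`s, one per configured classifier, with
#'   attribute `folds` holding the fold assignment.
#' @export
run_cv <- function(features, cfg = cv_config()) {
  manifest <- unique(features[, c("patient_id", "label")])
  folds <- stratified_patient_folds(manifest, cfg$n_folds, cfg$seed)
  fmap <- setNames(folds$fold, folds$patient_id)
  reports <- lapply(setNames(cfg$classifiers, cfg$classifiers), function(id) {
    frs <- lapply(seq_len(cfg$n_folds), function(k) {
      te <- features[fmap[features$patient_id] == k, , drop = FALSE]
      tr <- features[fmap[features$patient_id] != k, , drop = FALSE]
      train_and_score(tr, te, id, cfg, fold_id = k)
    })
    aggregate_cv(frs)
  })
  attr(reports, "folds") <- folds
  reports
}

#' Metric table shaped like a published performance table
#'
#' @param reports Output of [run_cv()] (or a named list of them keyed by
#'   feature-set label).
#' @return data.frame with one row per classifier and formatted
#'   `mean +/- SD` columns.
#' @export
cv_metric_table <- function(reports) {
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(classifier = id,
               sensitivity = fmt(r$mean["sensitivity"], r$sd["sensitivity"]),
               specificity = fmt(r$mean["specificity"], r$sd["specificity"]),
               accuracy = fmt(r$mean["accuracy"], r$sd["accuracy"]),
               auc = fmt(r$mean["auc"], r$sd["auc"]))
  }))
}
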