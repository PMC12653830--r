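#' Selection configuration
#'
#' The three-step cascade: variance threshold, univariate ANOVA, L1-penalized
#' logistic regression.
#'
#' @param variance_threshold Drop features with variance at or below this
#'   value, computed on the raw (pre-standardization) training features
#'   (default 0.05; subsumes zero-variance removal).
#' @param anova_alpha Keep features with ANOVA p-value below this level
#'   (default 0.05). Mutually exclusive with `top_k`.
#' @param top_k Alternative ANOVA rule: keep the `top_k` features by F
#'   statistic.
#' @param l1_C Inverse regularization strength of the L1 logistic step
#'   (default 0.5); mapped to the lasso penalty `lambda = 1 / (n * C)`.
#' @param standardize_before Standardize features (train statistics) before
#'   the L1 fit (default `TRUE`).
#' @return List with class `selection_config`.
#' @export
selection_config <- function(variance_threshold = 0.05, anova_alpha = 0.05,
                             top_k = NULL, l1_C = 0.5,
                             standardize_before = TRUE) {
  if (!is.null(top_k)) anova_alpha <- NULL
  if (is.null(anova_alpha) && is.null(top_k))
    stop("one of anova_alpha or top_k must be set")
  if (variance_threshold < 0 || l1_C <= 0)
    stop("thresholds must be positive")
  structure(list(variance_threshold = variance_threshold,
                 anova_alpha = anova_alpha, top_k = top_k, l1_C = l1_C,
                 standardize_before = standardize_before),
            class = "selection_config")
}

#' Variance filter
#'
#' Drops feature columns whose variance is at or below the threshold.
#'
#' @param x Numeric matrix or feature data.frame (rows = samples).
#' @param threshold Variance threshold (default 0.05).
#' @return Character vector of surviving column names.
#' @export
variance_filter <- function(x, threshold = 0.05) {
  x <- as.matrix(x)
  v <- apply(x, 2, var)
  keep <- colnames(x)[is.finite(v) & v > threshold]
  if (length(keep) == 0) stop("no features survive the variance filter")
  keep
}

#' Univariate ANOVA ranking
#'
#' One-way ANOVA F statistic and p-value of each feature between the two
#' label groups.
#'
#' @param x Numeric matrix (rows = samples).
#' @param labels 0/1 vector.
#' @return data.frame with `feature`, `F`, `p`, ordered as the columns of `x`.
#' @export
anova_rank <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  if (n0 < 2 || n1 < 2) stop("each class needs at least 2 samples")
  n <- n0 + n1
  m0 <- colMeans(x[labels == 0, , drop = FALSE])
  m1 <- colMeans(x[labels == 1, , drop = FALSE])
  gm <- (n0 * m0 + n1 * m1) / n
  ss_between <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  ss_within <- colSums((x[labels == 0, , drop = FALSE] -
                          matrix(m0, n0, ncol(x), byrow = TRUE))^2) +
               colSums((x[labels == 1, , drop = FALSE] -
                          matrix(m1, n1, ncol(x), byrow = TRUE))^2)
  df1 <- 1; df2 <- n - 2
  Fv <- (ss_between / df1) / (ss_within / df2)
  Fv[ss_within == 0 & ss_between == 0] <- 0
  Fv[ss_within == 0 & ss_between > 0] <- Inf
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  data.frame(feature = colnames(x), F = Fv, p = p, row.names = NULL)
}

#' L1-penalized logistic selection
#'
#' Fits an L1 logistic regression at inverse regularization strength `C` and
#' keeps features with non-zero coefficients. Features are expected to be
#' standardized by the caller when `standardize_before` is in force.
#'
#' @param x Numeric matrix (rows = samples).
#' @param labels 0/1 vector.
#' @param C Inverse regularization strength (default 0.5).
#' @param tol Coefficient magnitude below which a feature counts as dropped.
#' @return Character vector of surviving feature names (may be empty).
#' @export
l1_select <- function(x, labels, C = 0.5, tol = 1e-8) {
  x <- as.matrix(x)
  lam <- 1 / (nrow(x) * C)
  fit <- glmnet::glmnet(x, as.factor(labels), family = "binomial",
                        alpha = 1, lambda = lam, standardize = FALSE)
  b <- as.numeric(coef(fit))[-1]
  colnames(x)[abs(b) > tol]
}

#' Fit the three-step feature selector on training data
#'
#' Variance filter, ANOVA retention, standardization (training statistics)
#' and L1 logistic selection, in that order, using training rows only. The
#' returned object standardizes and subsets new data without touching its
#' labels.
#'
#' @param x Training feature matrix or data.frame.
#' @param labels Training 0/1 labels.
#' @param cfg A [selection_config()].
#' @return A `qc_selector`: list with `features` (final set), `center`,
#'   `scale` (train statistics for the final set) and the intermediate sets.
#' @export
fit_feature_selector <- function(x, labels, cfg = selection_config()) {
  x <- as.matrix(x)
  keep_var <- variance_filter(x, cfg$variance_threshold)
  x1 <- x[, keep_var, drop = FALSE]
  ar <- anova_rank(x1, labels)
  keep_anova <- if (!is.null(cfg$anova_alpha)) {
    ar$feature[ar$p < cfg$anova_alpha]
  } else {
    ar$feature[order(-ar$F)][seq_len(min(cfg$top_k, nrow(ar)))]
  }
  if (length(keep_anova) == 0)
    stop("no features survive the ANOVA step")
  x2 <- x1[, keep_anova, drop = FALSE]
  ctr <- colMeans(x2)
  scl <- apply(x2, 2, sd)
  scl[scl == 0] <- 1
  x2s <- if (cfg$standardize_before) scale(x2, ctr, scl) else x2
  keep_l1 <- l1_select(x2s, labels, cfg$l1_C)
  if (length(keep_l1) == 0)
    stop("L1 step zeroed every coefficient; increase C")
  structure(list(features = keep_l1,
                 center = ctr[keep_l1], scale = scl[keep_l1],
                 after_variance = keep_var, after_anova = keep_anova,
                 cfg = cfg),
            class = "qc_selector")
}

#' Apply a fitted selector to new data
#'
#' @param selector A `qc_selector` from [fit_feature_selector()].
#' @param x Feature matrix or data.frame with at least the selected columns.
#' @return Standardized numeric matrix restricted to the selected features.
#' @export
apply_feature_selector <- function(selector, x) {
  x <- as.matrix(x)[, selector$features, drop = FALSE]
  scale(x, selector$center, selector$scale)
}
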