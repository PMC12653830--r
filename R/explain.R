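#' Kernel SHAP attributions
#'
#' Model-agnostic Shapley estimates for a probability model. Coalition
#' values are expectations over a background (reference) set; attributions
#' solve the Shapley kernel-weighted least squares problem with the sum
#' constraint eliminated analytically, so local accuracy
#' (`base_value + sum(phi) == model_output`) holds exactly on every sample.
#' With `m` features, all `2^m` coalitions are enumerated when `m <= 11`;
#' otherwise coalitions are sampled by kernel weight (seeded).
#'
#' @param predict_fun Function mapping a feature matrix to class-1
#'   probabilities.
#' @param x Matrix of samples to explain (rows).
#' @param background Background feature matrix from the training fold;
#'   subsampled to at most `max_background` rows (seeded).
#' @param max_coalitions Coalition budget when sampling (default 2048).
#' @param max_background Cap on background rows (default 100).
#' @param seed Seed for the subsampling.
#' @return A `shap_attribution`: list with `phi` (samples x features),
#'   `base_value`, `model_output`.
#' @export
kernel_shap <- function(predict_fun, x, background, max_coalitions = 2048L,
                        max_background = 100L, seed = 0L) {
  x <- as.matrix(x); background <- as.matrix(background)
  if (nrow(background) == 0) stop("empty background set")
  m <- ncol(x)
  set.seed(seed)
  if (nrow(background) > max_background)
    background <- background[sample(nrow(background), max_background), ,
                             drop = FALSE]
  base_value <- mean(predict_fun(background))

  if (m == 1L) {
    out <- predict_fun(x)
    phi <- matrix(out - base_value, ncol = 1,
                  dimnames = list(NULL, colnames(x)))
    return(structure(list(phi = phi, base_value = base_value,
                          model_output = out),
                     class = "shap_attribution"))
  }

  # coalition design: rows are 0/1 masks excluding empty and full sets
  if (2^m - 2 <= max_coalitions) {
    Z <- t(sapply(1:(2^m - 2), function(k) as.integer(intToBits(k)[1:m])))
  } else {
    sizes <- 1:(m - 1)
    wt <- (m - 1) / (sizes * (m - sizes))
    draw <- sample(sizes, max_coalitions, replace = TRUE, prob = wt / sum(wt))
    Z <- t(vapply(draw, function(s) {
      z <- integer(m); z[sample(m, s)] <- 1L; z
    }, integer(m)))
    Z <- unique(Z)
  }
  s <- rowSums(Z)
  w <- (m - 1) / (choose(m, s) * s * (m - s))

  nb <- nrow(background)
  out <- predict_fun(x)
  phi <- matrix(0, nrow(x), m, dimnames = list(NULL, colnames(x)))
  for (i in seq_len(nrow(x))) {
    # E[f | coalition]: replace masked-out features by background rows
    v <- vapply(seq_len(nrow(Z)), function(r) {
      Xi <- background
      on <- Z[r, ] == 1L
      Xi[, on] <- matrix(x[i, on], nb, sum(on), byrow = TRUE)
      mean(predict_fun(Xi))
    }, numeric(1))
    # eliminate the constraint sum(phi) = f(x) - base via phi_m
    fx <- out[i]
    y <- v - base_value - Z[, m] * (fx - base_value)
    A <- Z[, -m, drop = FALSE] - Z[, m]
    WA <- A * w
    beta <- tryCatch(solve(crossprod(A, WA), crossprod(WA, y)),
                     error = function(e)
                       qr.coef(qr(sqrt(w) * A), sqrt(w) * y))
    beta[is.na(beta)] <- 0
    phi[i, -m] <- beta
    phi[i, m] <- (fx - base_value) - sum(beta)
  }
  structure(list(phi = phi, base_value = base_value, model_output = out),
            class = "shap_attribution")
}

#' Explain the best fold of a CV report
#'
#' Re-applies the best fold's fitted selector, uses its training-fold rows
#' as the SHAP background and explains the held-out test rows.
#'
#' @param report A `cv_report` from [run_cv()]/[aggregate_cv()].
#' @param features The feature table the report was computed from.
#' @param folds Fold assignment (attribute `folds` of [run_cv()] output).
#' @param seed Seed for SHAP sampling.
#' @return A `shap_attribution` with attribute `features` naming the
#'   selected feature set.
#' @export
explain_best_fold <- function(report, features, folds, seed = 0L) {
  bf <- report$best_fold
  fmap <- setNames(folds$fold, folds$patient_id)
  te <- features[fmap[features$patient_id] == bf$fold_id, , drop = FALSE]
  tr <- features[fmap[features$patient_id] != bf$fold_id, , drop = FALSE]
  fc <- feature_columns(features)
  xtr <- apply_feature_selector(bf$selector, tr[, fc])
  xte <- apply_feature_selector(bf$selector, te[, fc])
  att <- kernel_shap(function(z) predict_prob1(bf$model, z),
                     xte, xtr, seed = seed)
  attr(att, "features") <- bf$selector$features
  att
}

#' Rank features by mean absolute Shapley value
#'
#' @param attribution A `shap_attribution`.
#' @return data.frame `feature`, `mean_abs_shap`, ordered descending.
#' @export
summary_ranking <- function(attribution) {
  mas <- colMeans(abs(attribution$phi))
  data.frame(feature = names(mas)[order(-mas)],
             mean_abs_shap = unname(sort(mas, decreasing = TRUE)),
             row.names = NULL)
}

#' Beeswarm-style SHAP summary plot
#'
#' @param attribution A `shap_attribution`.
#' @param x The (standardized) feature matrix that was explained, used to
#'   color points by feature value.
#' @param top Number of features to show.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_shap_summary <- function(attribution, x, top = 15L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  rk <- summary_ranking(attribution)
  feats <- head(rk$feature, top)
  x <- as.matrix(x)
  df <- do.call(rbind, lapply(feats, function(f) {
    data.frame(feature = f, shap = attribution$phi[, f], value = x[, f])
  }))
  df$feature <- factor(df$feature, levels = rev(feats))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shap, y = .data$feature,
                                   color = .data$value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.7, size = 1) +
    ggplot2::scale_color_gradient(low = "#3b4cc0", high = "#b40426",
                                  name = "feature\nvalue") +
    ggplot2::labs(x = "SHAP value (impact on P(low quality))", y = NULL) +
    ggplot2::theme_minimal()
}
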