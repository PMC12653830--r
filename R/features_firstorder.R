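#' First-order intensity features
#'
#' The standard IBSI first-order set of exactly 18 features. Entropy and
#' Uniformity are histogram features and are computed from the supplied
#' discretized levels (the same levels fed to the texture matrices); all
#' other features are computed directly from the intensities. Variance,
#' skewness and kurtosis use population moments; kurtosis is not
#' excess-corrected.
#'
#' @param x Numeric vector of intensities inside the ROI mask (length >= 2).
#' @param levels Integer levels from [fbs_discretize()] on the same pixels;
#'   if `NULL`, a unit-width binning of `x` is used.
#' @return Named numeric vector of length 18.
#' @export
firstorder_features <- function(x, levels = NULL) {
  if (length(x) < 2) stop("need at least 2 pixels in the mask")
  if (is.null(levels)) levels <- fbs_discretize(x, 1)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  p <- tabulate(levels) / n
  p <- p[p > 0]
  in_robust <- x >= q[1] & x <= q[5]
  xr <- x[in_robust]
  c(Energy = sum(x^2),
    TotalEnergy = sum(x^2),  # unit pixel area; kept as a distinct column
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    P10 = q[1],
    P90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(xr)) mean(abs(xr - mean(xr))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
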