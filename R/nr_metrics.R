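#' Anisotropic total variation
#'
#' Sum of absolute horizontal and vertical neighbour differences; by default
#' normalized by the pixel count so slices of different size are comparable.
#' Noise raises TV, blurring lowers it.
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param normalized Divide by the number of pixels (default `TRUE`).
#' @return Scalar TV.
#' @export
total_variation <- function(slice, normalized = TRUE) {
  px <- slice_pixels(slice)
  tv <- 0
  if (ncol(px) > 1) tv <- tv + sum(abs(px[, -1] - px[, -ncol(px)]))
  if (nrow(px) > 1) tv <- tv + sum(abs(px[-1, ] - px[-nrow(px), ]))
  if (normalized) tv / length(px) else tv
}

# --- BRISQUE natural-scene-statistics front end -----------------------------
# MSCN coefficients, generalized-Gaussian fits, 36 features over two scales.

brisque_gaussian7 <- function() gaussian_kernel_1d(7 / 6)[2:8]  # 7-tap window

#' MSCN coefficients of an image
#'
#' Mean-subtracted contrast-normalized coefficients: local mean and standard
#' deviation from a 7x7 Gaussian window (sigma 7/6), stabilized by a small
#' constant.
#'
#' @param px 2D matrix with values in `[0, 1]`.
#' @param C Stabilizing constant, default `1/255`.
#' @return 2D matrix of MSCN coefficients.
#' @export
mscn_coefficients <- function(px, C = 1 / 255) {
  k <- brisque_gaussian7()
  k <- k / sum(k)
  mu <- cpp_sepconv2(px, k, k)
  sigma <- sqrt(pmax(cpp_sepconv2(px * px, k, k) - mu^2, 0))
  (px - mu) / (sigma + C)
}

# Moment-matching GGD fit: shape alpha and scale sigma.
.ggd_gam <- seq(0.2, 10, by = 0.001)
.ggd_rho <- (gamma(1 / .ggd_gam) * gamma(3 / .ggd_gam)) /
  gamma(2 / .ggd_gam)^2

fit_ggd <- function(x) {
  sig2 <- mean(x^2)
  E <- mean(abs(x))
  rho <- sig2 / max(E^2, .Machine$double.eps)
  alpha <- .ggd_gam[which.min(abs(.ggd_rho - rho))]
  c(alpha = alpha, sigma2 = sig2)
}

# Asymmetric GGD fit (standard BRISQUE estimator); returns shape, mean and
# the left/right variances.
fit_aggd <- function(x) {
  xl <- x[x < 0]; xr <- x[x >= 0]
  eps <- .Machine$double.eps
  sigl <- sqrt(mean(xl^2)); if (!length(xl) || !is.finite(sigl)) sigl <- 0
  sigr <- sqrt(mean(xr^2)); if (!length(xr) || !is.finite(sigr)) sigr <- 0
  gammahat <- (sigl + eps) / (sigr + eps)
  rhat <- mean(abs(x))^2 / max(mean(x^2), eps)
  rhatnorm <- rhat * (gammahat^3 + 1) * (gammahat + 1) /
    (gammahat^2 + 1)^2
  alpha <- .ggd_gam[which.min(abs(.ggd_rho - rhatnorm))]
  eta <- (sigr - sigl) * gamma(2 / alpha) / gamma(1 / alpha)
  c(alpha = alpha, eta = eta, sigma2_left = sigl^2, sigma2_right = sigr^2)
}

brisque_scale_features <- function(px) {
  m <- mscn_coefficients(px)
  g <- fit_ggd(as.vector(m))
  shifts <- list(H = m[, -1] * m[, -ncol(m)],
                 V = m[-1, ] * m[-nrow(m), ],
                 D1 = m[-1, -1] * m[-nrow(m), -ncol(m)],
                 D2 = m[-1, -ncol(m)] * m[-nrow(m), -1])
  c(g, unlist(lapply(shifts, function(s) fit_aggd(as.vector(s)))))
}

#' BRISQUE natural-scene-statistics features
#'
#' 18 features per scale (2 GGD parameters of the MSCN field + 4 AGGD
#' parameters for each of the 4 pairwise-product orientations) at the
#' native scale and at a 2x downsampled scale: 36 features total. The image
#' is first rescaled to `[0, 1]`.
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param min_size Smallest admissible image side (default 8).
#' @return Named numeric vector of length 36.
#' @export
brisque_features <- function(slice, min_size = 8) {
  px <- slice_pixels(slice)
  if (min(dim(px)) < min_size)
    stop("image too small for BRISQUE: need at least ", min_size, " pixels per side")
  rg <- max(px) - min(px)
  px <- if (rg > 0) (px - min(px)) / rg else px * 0
  f1 <- brisque_scale_features(px)
  # simple low-pass before dyadic decimation
  k <- c(0.25, 0.5, 0.25)
  low <- cpp_sepconv2(px, k, k)
  half <- low[seq(1, nrow(px), by = 2), seq(1, ncol(px), by = 2), drop = FALSE]
  f2 <- brisque_scale_features(half)
  out <- c(f1, f2)
  names(out) <- paste0(rep(c("s1_", "s2_"), each = 18),
                       rep(c("mscn_alpha", "mscn_sigma2",
                             paste0(rep(c("H", "V", "D1", "D2"), each = 4),
                                    "_", c("alpha", "eta", "sigma2_left",
                                           "sigma2_right"))), 2))
  out
}

.brisque_ref_cache <- new.env(parent = emptyenv())

brisque_reference <- function() {
  if (!is.null(.brisque_ref_cache$ref)) return(.brisque_ref_cache$ref)
  path <- system.file("extdata", "brisque_pristine_stats_synthetic.csv",
                      package = "dceqc")
  if (path == "") return(NULL)
  tab <- as.matrix(read.csv(path, row.names = 1))
  ref <- list(mean = tab[1, ],
              icov = solve(tab[-1, , drop = FALSE] +
                             diag(1e-3, ncol(tab))))
  .brisque_ref_cache$ref <- ref
  ref
}

#' BRISQUE-style quality score
#'
#' Maps the 36 natural-scene-statistics features to a scalar by Mahalanobis
#' distance to pristine-image statistics (mean and covariance) fitted on
#' clean synthetic phantom slices and shipped as a plain-text asset. Higher
#' scores indicate worse quality; the score is finite on degenerate
#' (constant) images. If the reference asset is missing the features are
#' returned with an `NA` score.
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param min_size Smallest admissible image side (default 32; the
#'   extraction pipeline relaxes this for corner-band crops).
#' @return Scalar score with attribute `nss` holding the 36 features.
#' @export
brisque_score <- function(slice, min_size = 32) {
  f <- brisque_features(slice, min_size = min_size)
  ref <- brisque_reference()
  score <- if (is.null(ref)) NA_real_ else {
    d <- f - ref$mean
    sqrt(max(0, sum(d * (ref$icov %*% d))))
  }
  attr(score, "nss") <- f
  score
}
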