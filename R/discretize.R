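#' Derive a fixed bin width from ROI intensity ranges
#'
#' Mean ROI intensity range divided by a fixed bin number; the result is
#' rounded to the nearest integer when it is at least one. This is how a
#' bin width on the native intensity scale (e.g. 54 for breast DCE-MRI with
#' a mean range near 3456 and FBN 64) is obtained.
#'
#' @param roi_intensity_ranges Positive numeric vector of per-ROI ranges.
#' @param fbn Fixed bin number (>= 2), default 64.
#' @return Scalar bin width.
#' @export
derive_bin_width <- function(roi_intensity_ranges, fbn = 64L) {
  if (length(roi_intensity_ranges) == 0)
    stop("no intensity ranges supplied")
  if (any(roi_intensity_ranges <= 0)) stop("ranges must be positive")
  if (fbn < 2) stop("fbn must be >= 2")
  w <- mean(roi_intensity_ranges) / fbn
  if (w >= 1) round(w) else w
}

#' Fixed-bin-size discretization
#'
#' IBSI FBS rule: `level(x) = floor((x - min(x)) / w) + 1`, referenced to the
#' ROI minimum. The number of gray levels is the maximum assigned level.
#'
#' @param x Numeric vector (pixels inside the ROI mask).
#' @param bin_width Positive bin width `w`.
#' @return Integer vector of levels (>= 1) with attribute `ng` = number of
#'   gray levels.
#' @export
fbs_discretize <- function(x, bin_width) {
  if (length(x) == 0) stop("empty mask")
  if (bin_width <= 0) stop("bin_width must be positive")
  lev <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  attr(lev, "ng") <- max(lev)
  lev
}
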