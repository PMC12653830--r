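#' ROI configuration
#'
#' @param corner_fraction Side of each corner square as a fraction of image
#'   height and width (default 1/8).
#' @param snr_epsilon Stabilizer added to the SNR denominator.
#' @return List with class `roi_config`.
#' @export
roi_config <- function(corner_fraction = 1 / 8, snr_epsilon = 1e-6) {
  if (corner_fraction <= 0 || corner_fraction > 0.5)
    stop("corner_fraction must be in (0, 1/2]")
  structure(list(corner_fraction = corner_fraction,
                 snr_epsilon = snr_epsilon),
            class = "roi_config")
}

#' Corner squares of a slice
#'
#' Anchors one square of size `floor(H*f) x floor(W*f)` flush to each image
#' corner and scores it with a signal-to-noise ratio (mean over population
#' standard deviation, epsilon-stabilized). Low SNR marks anatomy-free
#' noise-dominated corners.
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param cfg An `roi_config`.
#' @return Named list of four entries `TL`, `TR`, `BL`, `BR`, each with
#'   `row_range`/`col_range` (half-open 0-based integer intervals) and `snr`.
#' @export
corner_squares <- function(slice, cfg = roi_config()) {
  px <- slice_pixels(slice)
  H <- nrow(px); W <- ncol(px)
  h <- floor(H * cfg$corner_fraction)
  w <- floor(W * cfg$corner_fraction)
  if (h < 2 || w < 2)
    stop("corner squares smaller than 2x2; image too small for fraction ",
         cfg$corner_fraction)
  ranges <- list(
    TL = list(row_range = c(0L, h), col_range = c(0L, w)),
    TR = list(row_range = c(0L, h), col_range = c(W - w, W)),
    BL = list(row_range = c(H - h, H), col_range = c(0L, w)),
    BR = list(row_range = c(H - h, H), col_range = c(W - w, W)))
  lapply(stats::setNames(names(ranges), names(ranges)), function(k) {
    rg <- ranges[[k]]
    vals <- px[(rg$row_range[1] + 1):rg$row_range[2],
               (rg$col_range[1] + 1):rg$col_range[2]]
    sq <- rg
    sq$corner <- k
    sq$snr <- corner_snr_values(vals, cfg)
    sq
  })
}

corner_snr_values <- function(vals, cfg = roi_config()) {
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  mu / (sigma + cfg$snr_epsilon)
}

#' SNR of one corner square
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param square One entry of [corner_squares()].
#' @param cfg An `roi_config`.
#' @return Scalar SNR = mean / (population SD + epsilon).
#' @export
corner_snr <- function(slice, square, cfg = roi_config()) {
  px <- slice_pixels(slice)
  vals <- px[(square$row_range[1] + 1):square$row_range[2],
             (square$col_range[1] + 1):square$col_range[2]]
  corner_snr_values(vals, cfg)
}

# Admissible (non-diagonal) corner pairs in tie-break order.
.nondiag_pairs <- list(c("TL", "TR"), c("BL", "BR"), c("TL", "BL"),
                       c("TR", "BR"))

#' Select the two background corners
#'
#' Among the four non-diagonal corner pairs, picks the pair with the lowest
#' total SNR; diagonal pairs are never admissible. Ties are broken by the
#' fixed order (TL,TR) < (BL,BR) < (TL,BL) < (TR,BR) so runs are
#' reproducible.
#'
#' @param squares Output of [corner_squares()].
#' @return List with `corners` (character pair), `squares` (the two square
#'   descriptors) and `snr_sum`.
#' @export
select_background_corners <- function(squares) {
  snr <- vapply(squares, function(s) s$snr, numeric(1))
  sums <- vapply(.nondiag_pairs, function(p) snr[[p[1]]] + snr[[p[2]]],
                 numeric(1))
  best <- .nondiag_pairs[[which.min(sums)]]  # which.min keeps first on ties
  list(corners = best,
       squares = squares[best],
       snr_sum = min(sums))
}

#' Build ROI masks
#'
#' `whole_mask()` returns an all-true mask over the slice; `background_mask()`
#' the union of the two selected corner squares.
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param pair Output of [select_background_corners()].
#' @return A `roi_mask`: list with logical `mask` and `roi_kind`.
#' @export
background_mask <- function(slice, pair) {
  px <- slice_pixels(slice)
  m <- matrix(FALSE, nrow(px), ncol(px))
  for (sq in pair$squares) {
    m[(sq$row_range[1] + 1):sq$row_range[2],
      (sq$col_range[1] + 1):sq$col_range[2]] <- TRUE
  }
  structure(list(mask = m, roi_kind = "background", corners = pair$corners),
            class = "roi_mask")
}

#' @rdname background_mask
#' @export
whole_mask <- function(slice) {
  px <- slice_pixels(slice)
  structure(list(mask = matrix(TRUE, nrow(px), ncol(px)), roi_kind = "whole"),
            class = "roi_mask")
}

#' Locate the background ROI of a slice in one call
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param cfg An `roi_config`.
#' @return A background `roi_mask`.
#' @export
detect_background_roi <- function(slice, cfg = roi_config()) {
  background_mask(slice, select_background_corners(corner_squares(slice, cfg)))
}

slice_pixels <- function(slice) {
  if (inherits(slice, "qc_slice")) slice$pixels else as.matrix(slice)
}
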