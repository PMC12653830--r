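#' Filter-bank configuration
#'
#' @param log_sigmas Laplacian-of-Gaussian scales, in pixels (default
#'   `c(2, 3, 4, 5)`).
#' @param wavelet_name Wavelet family; `"coif1"` is the only built-in.
#' @param wavelet_level Decomposition level (1).
#' @return List with class `filter_config`.
#' @export
filter_config <- function(log_sigmas = c(2, 3, 4, 5), wavelet_name = "coif1",
                          wavelet_level = 1L) {
  if (any(log_sigmas <= 0)) stop("LoG sigmas must be positive")
  if (wavelet_name != "coif1") stop("only the coif1 wavelet is built in")
  if (wavelet_level != 1L) stop("only a single decomposition level is supported")
  structure(list(log_sigmas = log_sigmas, wavelet_name = wavelet_name,
                 wavelet_level = wavelet_level),
            class = "filter_config")
}

gaussian_kernel_1d <- function(sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Laplacian-of-Gaussian response
#'
#' Gaussian smoothing at scale `sigma` (separable kernel truncated at three
#' sigma) followed by the discrete 5-point Laplacian; symmetric boundary
#' handling throughout.
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param sigma Scale in pixels (> 0).
#' @return 2D matrix, same size as the input.
#' @export
log_filter <- function(slice, sigma) {
  px <- slice_pixels(slice)
  if (sigma <= 0) stop("sigma must be positive")
  k <- gaussian_kernel_1d(sigma)
  if (length(k) > 2 * max(dim(px)))
    stop("LoG kernel exceeds image extent at sigma ", sigma)
  sm <- cpp_sepconv2(px, k, k)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  cpp_conv2(sm, lap)
}

# coif1 analysis low-pass filter (standard published coefficients); the
# high-pass is the quadrature mirror.
.coif1_lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
               0.852572020212255, 0.337897662457809, -0.072732619512854)

coif1_filters <- function() {
  lo <- .coif1_lo
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi)
}

#' One-level 2D discrete wavelet decomposition
#'
#' Separable coif1 analysis with symmetric extension and dyadic decimation.
#' Subband tags: the first letter is the filter applied along rows
#' (vertical direction), the second along columns. Each subband is brought
#' back to the input size by zero-order (pixel-replication) upsampling so a
#' single ROI mask applies to every filtered image.
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param cfg A `filter_config`.
#' @return Named list of four matrices `LL`, `LH`, `HL`, `HH`, each the size
#'   of the input.
#' @export
wavelet_decompose <- function(slice, cfg = filter_config()) {
  px <- slice_pixels(slice)
  f <- coif1_filters()
  if (min(dim(px)) < length(f$lo))
    stop("image smaller than the wavelet filter length")
  L <- cpp_dwt_axis(px, f$lo, 0L)
  H <- cpp_dwt_axis(px, f$hi, 0L)
  bands <- list(LL = cpp_dwt_axis(L, f$lo, 1L),
                LH = cpp_dwt_axis(L, f$hi, 1L),
                HL = cpp_dwt_axis(H, f$lo, 1L),
                HH = cpp_dwt_axis(H, f$hi, 1L))
  lapply(bands, upsample_nn, target = dim(px))
}

upsample_nn <- function(m, target) {
  r <- rep(seq_len(nrow(m)), each = 2)[seq_len(target[1])]
  c <- rep(seq_len(ncol(m)), each = 2)[seq_len(target[2])]
  r[r > nrow(m)] <- nrow(m)
  c[c > ncol(m)] <- ncol(m)
  m[r, c, drop = FALSE]
}

#' Full filter bank of a slice
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @param cfg A `filter_config`.
#' @return Named list of 9 filtered images: `original`, `wavelet-LL`,
#'   `wavelet-LH`, `wavelet-HL`, `wavelet-HH`, `log-sigma-2` .. `log-sigma-5`
#'   (one per configured sigma), all the size of the input.
#' @export
filter_bank <- function(slice, cfg = filter_config()) {
  px <- slice_pixels(slice)
  out <- list(original = px)
  wb <- wavelet_decompose(px, cfg)
  names(wb) <- paste0("wavelet-", names(wb))
  out <- c(out, wb)
  for (s in cfg$log_sigmas)
    out[[paste0("log-sigma-", format(s, trim = TRUE))]] <- log_filter(px, s)
  out
}
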