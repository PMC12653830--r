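#' Extraction configuration
#'
#' Bundles the filter bank, discretization and ROI settings and asserts the
#' feature-count identities at build time: 18 first-order + 22 GLCM +
#' 14 GLDM + 16 GLRLM + 16 GLSZM + 5 NGTDM = 91 features per filtered
#' image, 91 x 9 filtered images = 819 radiomic features, + 2 no-reference
#' metrics = 821 per ROI.
#'
#' @param bin_width Fixed bin size on the native intensity scale (default 54,
#'   the width obtained from a mean ROI range near 3456 at FBN 64; set 1 for
#'   the no-discretization regime).
#' @param discretize_on `"raw"`: `bin_width` refers to the pre-normalization
#'   intensity scale and is mapped through the per-slice z-score transform
#'   (width / slice SD) before binning the filtered images. `"normalized"`:
#'   the width is applied literally on the z-scored scale.
#' @param filters A [filter_config()].
#' @param roi An [roi_config()].
#' @param gldm_alpha Dependence tolerance for GLDM (default 0).
#' @return List with class `extraction_config`.
#' @export
extraction_config <- function(bin_width = 54, discretize_on = c("raw", "normalized"),
                              filters = filter_config(), roi = roi_config(),
                              gldm_alpha = 0L) {
  discretize_on <- match.arg(discretize_on)
  if (bin_width <= 0) stop("bin_width must be positive")
  per_class <- c(firstorder = 18L, glcm = 22L, gldm = 14L, glrlm = 16L,
                 glszm = 16L, ngtdm = 5L)
  n_filters <- 5L + length(filters$log_sigmas)
  stopifnot(sum(per_class) == 91L,
            sum(per_class[-1]) == 73L,
            91L * n_filters == 819L,
            sum(per_class * n_filters) + 2L == 821L)
  structure(list(bin_width = bin_width, discretize_on = discretize_on,
                 filters = filters, roi = roi, gldm_alpha = gldm_alpha,
                 per_class = per_class, n_filters = n_filters),
            class = "extraction_config")
}

filtered_roi_features <- function(fimg, mask, w_eff, gldm_alpha) {
  lv <- level_image(fimg, mask, w_eff)
  vals <- fimg[mask]
  lev_in <- lv[lv > 0]
  attr(lev_in, "ng") <- attr(lv, "ng")
  c(firstorder = firstorder_features(vals, lev_in),
    glcm = glcm_features(lv),
    gldm = gldm_features(lv, alpha = gldm_alpha),
    glrlm = glrlm_features(lv),
    glszm = glszm_features(lv),
    ngtdm = ngtdm_features(lv))
}

# contiguous crop holding both background squares: the bounding band of the
# union (full-width or full-height strip for a non-diagonal pair)
background_crop <- function(px, bg) {
  rows <- range(unlist(lapply(bg$mask_squares, function(s) s$row_range)))
  cols <- range(unlist(lapply(bg$mask_squares, function(s) s$col_range)))
  px[(rows[1] + 1):rows[2], (cols[1] + 1):cols[2], drop = FALSE]
}

#' Extract the full feature vector(s) of one slice
#'
#' Z-scores the slice (whole-slice statistics), applies the 9-image filter
#' bank, discretizes with the fixed bin size, and computes 819 radiomic
#' features plus BRISQUE and total variation (821 per ROI). In `"combined"`
#' mode the background features are appended with the `"_bg"` suffix
#' (1642 values). Feature order is deterministic.
#'
#' @param slice A `qc_slice` or 2D matrix of raw intensities.
#' @param roi_mode `"whole"`, `"background"` or `"combined"`.
#' @param cfg An [extraction_config()].
#' @return Named numeric vector of length 821 (single ROI) or 1642
#'   (combined).
#' @export
extract_features <- function(slice, roi_mode = c("combined", "whole", "background"),
                             cfg = extraction_config()) {
  roi_mode <- match.arg(roi_mode)
  px <- slice_pixels(slice)
  z <- zscore_normalize(px)
  sd_raw <- attr(z, "zscore_sd")
  w_eff <- if (cfg$discretize_on == "raw") cfg$bin_width / sd_raw
           else cfg$bin_width
  bank <- filter_bank(z, cfg$filters)

  pair <- select_background_corners(corner_squares(px, cfg$roi))
  masks <- list()
  if (roi_mode %in% c("whole", "combined"))
    masks$whole <- whole_mask(px)$mask
  if (roi_mode %in% c("background", "combined")) {
    bm <- background_mask(px, pair)
    masks$background <- bm$mask
  }

  per_roi <- lapply(names(masks), function(kind) {
    mask <- masks[[kind]]
    rad <- unlist(lapply(names(bank), function(tag) {
      v <- filtered_roi_features(bank[[tag]], mask, w_eff, cfg$gldm_alpha)
      names(v) <- paste0(tag, "_", sub("\\.", "_", names(v)))
      v
    }))
    nr_img <- if (kind == "whole") z else {
      bg <- list(mask_squares = pair$squares)
      background_crop(z, bg)
    }
    nr <- c(NR_brisque = as.numeric(brisque_score(nr_img, min_size = 4)),
            NR_total_variation = total_variation(nr_img))
    v <- c(rad, nr)
    if (kind == "background") names(v) <- paste0(names(v), "_bg")
    v
  })
  out <- unlist(per_roi)
  expected <- if (roi_mode == "combined") 1642L else 821L
  stopifnot(length(out) == expected)
  out
}

#' Extract a cohort feature table
#'
#' Runs slice sampling and feature extraction for every patient in a cohort
#' and returns one row per (patient, slice).
#'
#' @param cohort Either a manifest data.frame with `patient_id`,
#'   `volume_path`, `label` columns (volumes read from disk) or a list as
#'   returned by [generate_cohort()] with in-memory volumes.
#' @param scenario `"twelve_slice"` or `"middle_slice"`.
#' @param roi_mode `"combined"`, `"whole"` or `"background"`.
#' @param cfg An [extraction_config()].
#' @param verbose Print progress.
#' @return data.frame with `patient_id`, `slice_index`, `label` and one
#'   column per feature, in deterministic order.
#' @export
extract_cohort <- function(cohort, scenario = c("middle_slice", "twelve_slice"),
                           roi_mode = c("combined", "whole", "background"),
                           cfg = extraction_config(), verbose = FALSE) {
  scenario <- match.arg(scenario)
  roi_mode <- match.arg(roi_mode)
  if (is.data.frame(cohort)) {
    manifest <- cohort
    get_vol <- function(i) read_volume(manifest$volume_path[i],
                                       patient_id = manifest$patient_id[i])
  } else {
    manifest <- cohort$manifest
    get_vol <- function(i) cohort$volumes[[i]]
  }
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    vol <- get_vol(i)
    slices <- sample_slices(vol, scenario)
    feats <- lapply(slices, function(s) extract_features(s, roi_mode, cfg))
    rows[[i]] <- data.frame(
      patient_id = manifest$patient_id[i],
      slice_index = vapply(slices, function(s) s$slice_index, integer(1)),
      label = manifest$label[i],
      do.call(rbind, feats),
      check.names = FALSE)
    if (verbose) message("extracted ", manifest$patient_id[i],
                         " (", i, "/", nrow(manifest), ")")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Columns of a feature table that hold features
#'
#' @param table A feature data.frame from [extract_cohort()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "slice_index", "label"))
}
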