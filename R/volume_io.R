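#' Read a 3D MRI volume from a NIfTI file
#'
#' Loads one post-contrast 3D volume and infers the through-plane (slice)
#' axis from the voxel spacing in the header: the axis with the largest
#' spacing is taken as through-plane, which is the usual situation for
#' anisotropic DCE acquisitions. The inference can be overridden.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param slice_axis Optional integer in 1..3 overriding the inferred
#'   through-plane axis.
#' @param patient_id Identifier attached to the volume; defaults to the file
#'   name without extension.
#' @param orientation `"axial"` or `"sagittal"`; metadata only.
#' @return A `qc_volume` object: list with `voxels` (3D array), `slice_axis`,
#'   `patient_id`, `orientation`, `spacing`.
#' @export
read_volume <- function(path, slice_axis = NULL, patient_id = NULL,
                        orientation = c("axial", "sagittal")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) {
    if (length(dim(arr)) == 4L)
      stop("4D image: pass a single post-contrast phase, not the DCE series")
    stop("expected a 3D image, got ", length(dim(arr)), "D")
  }
  attributes(arr) <- list(dim = dim(arr))  # drop header attributes
  spacing <- tryCatch(RNifti::pixdim(img)[seq_len(3)],
                      error = function(e) c(1, 1, 1))
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  qc_volume(arr, slice_axis = slice_axis, patient_id = patient_id,
            orientation = orientation, spacing = spacing)
}

#' Construct a volume object from an array
#'
#' @param voxels 3D numeric array of intensities.
#' @param slice_axis Through-plane axis (1..3); if `NULL`, inferred as the
#'   axis with the largest voxel spacing (ties resolved to the last axis).
#' @param patient_id Identifier string.
#' @param orientation `"axial"` or `"sagittal"`.
#' @param spacing Numeric length-3 voxel spacing.
#' @return A `qc_volume` object.
#' @export
qc_volume <- function(voxels, slice_axis = NULL, patient_id = "anon",
                      orientation = "axial", spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("non-finite voxels in volume")
  if (is.null(slice_axis)) {
    slice_axis <- which(spacing == max(spacing))
    slice_axis <- slice_axis[length(slice_axis)]
  }
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  structure(list(voxels = voxels, slice_axis = slice_axis,
                 patient_id = patient_id, orientation = orientation,
                 spacing = spacing),
            class = "qc_volume")
}

#' @export
print.qc_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<qc_volume> %s  %dx%dx%d  slice axis %d (%d slices), %s\n",
              x$patient_id, d[1], d[2], d[3], x$slice_axis,
              d[x$slice_axis], x$orientation))
  invisible(x)
}

n_slices <- function(vol) dim(vol$voxels)[vol$slice_axis]

#' Extract a 2D slice from a volume
#'
#' @param vol A `qc_volume`.
#' @param index 1-based slice index along the through-plane axis.
#' @param scenario Sampling scenario tag attached to the slice.
#' @return A `qc_slice`: list with `pixels` (2D matrix), `patient_id`,
#'   `slice_index` (0-based, matching the sampling contracts), `scenario`.
#' @export
get_slice <- function(vol, index, scenario = c("twelve_slice", "middle_slice")) {
  scenario <- match.arg(scenario)
  Z <- n_slices(vol)
  if (index < 1L || index > Z) stop("slice index out of range")
  px <- switch(vol$slice_axis,
               vol$voxels[index, , ],
               vol$voxels[, index, ],
               vol$voxels[, , index])
  qc_slice(px, patient_id = vol$patient_id, slice_index = index - 1L,
           scenario = scenario)
}

#' @rdname get_slice
#' @param pixels 2D numeric matrix.
#' @param patient_id Identifier string.
#' @param slice_index 0-based position along the slice axis.
#' @export
qc_slice <- function(pixels, patient_id = "anon", slice_index = 0L,
                     scenario = "middle_slice") {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  structure(list(pixels = pixels, patient_id = patient_id,
                 slice_index = as.integer(slice_index), scenario = scenario),
            class = "qc_slice")
}

#' Z-score normalize a slice
#'
#' Standardizes the whole 2D slice to zero mean and unit population standard
#' deviation. The affine map is computed from the full slice, so whole-image
#' and background ROIs taken from the result are on the same scale.
#'
#' @param slice A `qc_slice` or 2D matrix.
#' @return Object of the same kind with standardized pixels; attributes
#'   `zscore_mean` and `zscore_sd` record the transform.
#' @export
zscore_normalize <- function(slice) {
  px <- if (inherits(slice, "qc_slice")) slice$pixels else as.matrix(slice)
  mu <- mean(px)
  sigma <- sqrt(mean((px - mu)^2))  # population SD
  if (sigma == 0) stop("zero-variance slice cannot be z-score normalized")
  out <- (px - mu) / sigma
  if (inherits(slice, "qc_slice")) {
    slice$pixels <- out
    attr(slice, "zscore_mean") <- mu
    attr(slice, "zscore_sd") <- sigma
    slice
  } else {
    attr(out, "zscore_mean") <- mu
    attr(out, "zscore_sd") <- sigma
    out
  }
}

#' Twelve-slice sampling indices (scenario 1)
#'
#' Splits the through-plane range into thirds and draws 3 evenly spaced
#' slices from the bottom third, 6 from the middle third and 3 from the top
#' third. Even spacing uses linearly spaced positions inclusive of the third
#' boundaries, rounded to the nearest integer; collisions are resolved by
#' shifting to the nearest unused in-range index (ties to the lower index).
#'
#' @param Z Number of slices (>= 12) or a `qc_volume`.
#' @return Sorted integer vector of 12 distinct 0-based indices.
#' @export
twelve_slice_indices <- function(Z) {
  if (inherits(Z, "qc_volume")) Z <- n_slices(Z)
  Z <- as.integer(Z)
  if (Z < 12L) stop("insufficient slices: need at least 12, got ", Z)
  t1 <- floor(Z / 3); t2 <- floor(2 * Z / 3)
  lin <- function(a, b, n) {
    if (n == 1L) return(round((a + b) / 2))
    round(a + (b - a) * (seq_len(n) - 1) / (n - 1))
  }
  cand <- c(lin(0, t1 - 1, 3L), lin(t1, t2 - 1, 6L), lin(t2, Z - 1, 3L))
  used <- rep(FALSE, Z)
  out <- integer(12)
  for (i in seq_along(cand)) {
    k <- cand[i]
    if (!used[k + 1L]) {
      out[i] <- k
    } else {
      # nearest unused index, lower index on ties
      free <- which(!used) - 1L
      d <- abs(free - k)
      out[i] <- free[order(d, free)][1L]
    }
    used[out[i] + 1L] <- TRUE
  }
  sort(out)
}

#' Middle-slice index (scenario 2)
#'
#' @param Z Number of slices or a `qc_volume`.
#' @return 0-based index `floor(Z / 2)`.
#' @export
middle_slice_index <- function(Z) {
  if (inherits(Z, "qc_volume")) Z <- n_slices(Z)
  if (Z < 1L) stop("empty volume")
  as.integer(floor(Z / 2))
}

#' Sample slices from a volume under either scenario
#'
#' @param vol A `qc_volume`.
#' @param scenario `"twelve_slice"` (12 slices, 3/6/3 across thirds) or
#'   `"middle_slice"` (single middle slice).
#' @return List of `qc_slice` objects.
#' @export
sample_slices <- function(vol, scenario = c("twelve_slice", "middle_slice")) {
  scenario <- match.arg(scenario)
  idx0 <- if (scenario == "twelve_slice") twelve_slice_indices(vol)
          else middle_slice_index(vol)
  lapply(idx0, function(i) get_slice(vol, i + 1L, scenario = scenario))
}

#' Read a cohort manifest CSV
#'
#' Expects columns `patient_id`, `volume_path`, `label` with label 0 = high
#' quality and 1 = low quality.
#'
#' @param path CSV file path.
#' @return data.frame with validated columns.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "volume_path", "label")
  if (!all(req %in% names(m)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(m$patient_id)) stop("duplicate patient_id in manifest")
  if (!all(m$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  m[, req]
}
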