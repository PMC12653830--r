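#' Synthetic breast-MRI phantom specification
#'
#' Describes one labeled volume: an elliptical "anatomy" region with smooth
#' internal texture over a dark air background, a bright chest-wall band at
#' the bottom of each slice, air noise, and a degradation specification
#' whose severity determines the quality label. Intensities live on a
#' DCE-like native scale (anatomy around 3000-3900) so the default fixed
#' bin width of 54 yields roughly 64 gray levels on the whole-image ROI.
#'
#' @param shape `(H, W, Z)` integer vector.
#' @param ellipse List `center` (row, col fractions), `axes` (row, col
#'   fractions of H and W), `intensity`.
#' @param chest_band List `intensity`, `extent` (fraction of rows at the
#'   bottom).
#' @param air_noise_sigma Baseline air noise SD (native units).
#' @param degradation A [degradation_spec()].
#' @param seed Integer seed; the volume is fully reproducible.
#' @return List with class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 20L),
                         ellipse = list(center = c(0.58, 0.5),
                                        axes = c(0.27, 0.33),
                                        intensity = 3400),
                         chest_band = list(intensity = 1200, extent = 0.08),
                         air_noise_sigma = 12,
                         degradation = degradation_spec(),
                         seed = 0L) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (ellipse$center[1] + ellipse$axes[1] > 1 ||
      ellipse$center[2] + ellipse$axes[2] > 1)
    stop("anatomy ellipse must fit inside the frame")
  if (ellipse$intensity < 0 || chest_band$intensity < 0)
    stop("intensities must be non-negative")
  structure(list(shape = as.integer(shape), ellipse = ellipse,
                 chest_band = chest_band, air_noise_sigma = air_noise_sigma,
                 degradation = degradation, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Degradation specification
#'
#' Severity score `s = noise_sigma/60 + blur_sigma/1.5 + zebra_amplitude/0.2
#' + ghost_amplitude/0.25` (each term scaled by a severity unit); the label
#' is 1 (low quality) when `s >= 1`.
#'
#' @param noise_sigma Additive noise SD (native units).
#' @param blur_sigma Gaussian blur SD in pixels.
#' @param zebra_amplitude,zebra_period Multiplicative sinusoidal stripe
#'   modulation depth and period in pixels.
#' @param ghost_shift,ghost_amplitude Column shift (pixels) and relative
#'   amplitude of the added attenuated copy.
#' @param rician Use Rician (magnitude) noise instead of Gaussian.
#' @return List with class `degradation_spec` and fields including the
#'   derived `severity` and `label`.
#' @export
degradation_spec <- function(noise_sigma = 0, blur_sigma = 0,
                             zebra_amplitude = 0, zebra_period = 8,
                             ghost_shift = 0, ghost_amplitude = 0,
                             rician = FALSE) {
  stopifnot(noise_sigma >= 0, blur_sigma >= 0, zebra_amplitude >= 0,
            ghost_amplitude >= 0)
  severity <- noise_sigma / 60 + blur_sigma / 1.5 +
    zebra_amplitude / 0.2 + ghost_amplitude / 0.25
  structure(list(noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 zebra_amplitude = zebra_amplitude,
                 zebra_period = zebra_period, ghost_shift = ghost_shift,
                 ghost_amplitude = ghost_amplitude, rician = rician,
                 severity = severity, label = as.integer(severity >= 1)),
            class = "degradation_spec")
}

clean_phantom_array <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]; Z <- spec$shape[3]
  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  cz <- (Z + 1) / 2
  arr <- array(0, dim = spec$shape)
  for (z in seq_len(Z)) {
    # ellipsoid cross-section: axes shrink towards the volume ends
    shrink <- sqrt(pmax(0, 1 - ((z - cz) / (Z / 2 + 0.5))^2))
    a <- spec$ellipse$axes[1] * H * shrink
    b <- spec$ellipse$axes[2] * W * shrink
    sl <- matrix(0, H, W)
    if (a >= 1 && b >= 1) {
      inside <- ((r - spec$ellipse$center[1] * H) / a)^2 +
        ((c_ - spec$ellipse$center[2] * W) / b)^2 <= 1
      # smooth internal texture: radial gradient plus blurred noise
      tex <- cpp_sepconv2(matrix(rnorm(H * W), H, W),
                          gaussian_kernel_1d(2), gaussian_kernel_1d(2))
      grad <- 1 - 0.25 * ((r - spec$ellipse$center[1] * H)^2 / a^2 +
                            (c_ - spec$ellipse$center[2] * W)^2 / b^2)
      sl[inside] <- spec$ellipse$intensity * grad[inside] +
        600 * tex[inside]
    }
    band_rows <- r > (1 - spec$chest_band$extent) * H
    sl[band_rows] <- pmax(sl[band_rows], spec$chest_band$intensity *
                            (0.9 + 0.1 * sin(c_[band_rows] / 7)))
    sl <- sl + rnorm(H * W, sd = spec$air_noise_sigma)
    arr[, , z] <- pmax(sl, 0)
  }
  arr
}

#' Generate a phantom volume
#'
#' Builds the clean anatomy volume from the spec's seed and applies the
#' degradation chain (blur, zebra stripes, ghosting, then noise).
#'
#' @param spec A [phantom_spec()].
#' @return A `qc_volume` with through-plane axis 3 and attribute `label`.
#' @export
generate_phantom <- function(spec) {
  set.seed(spec$seed)
  arr <- clean_phantom_array(spec)
  arr <- degrade_array(arr, spec$degradation)
  vol <- qc_volume(arr, slice_axis = 3L,
                   patient_id = sprintf("phantom%06d", spec$seed),
                   spacing = c(1, 1, 3))
  attr(vol, "label") <- spec$degradation$label
  attr(vol, "spec") <- spec
  vol
}

#' Apply a degradation chain to a volume
#'
#' Order: Gaussian blur, multiplicative sinusoidal zebra stripes, shifted
#' attenuated ghost copy, additive Gaussian (or Rician magnitude) noise.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param volume A `qc_volume` or 3D array.
#' @param spec A [degradation_spec()].
#' @return Same type as the input with degraded voxels.
#' @export
degrade_volume <- function(volume, spec) {
  if (inherits(volume, "qc_volume")) {
    volume$voxels <- degrade_array(volume$voxels, spec)
    volume
  } else {
    degrade_array(volume, spec)
  }
}

degrade_array <- function(arr, spec) {
  H <- dim(arr)[1]; W <- dim(arr)[2]; Z <- dim(arr)[3]
  r <- matrix(seq_len(H), H, W)
  for (z in seq_len(Z)) {
    sl <- arr[, , z]
    if (spec$blur_sigma > 0) {
      k <- gaussian_kernel_1d(spec$blur_sigma)
      sl <- cpp_sepconv2(sl, k, k)
    }
    if (spec$zebra_amplitude > 0)
      sl <- sl * (1 + spec$zebra_amplitude *
                    sin(2 * pi * r / spec$zebra_period))
    if (spec$ghost_amplitude > 0 && spec$ghost_shift != 0) {
      shift <- ((seq_len(W) - 1 + spec$ghost_shift) %% W) + 1
      sl <- sl + spec$ghost_amplitude * sl[, shift]
    }
    if (spec$noise_sigma > 0) {
      if (spec$rician) {
        n1 <- matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
        n2 <- matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
        sl <- sqrt((sl + n1)^2 + n2^2)
      } else {
        sl <- sl + matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
      }
    }
    arr[, , z] <- sl
  }
  arr
}

# severity draws with a guard band: class 0 stays well below the label
# threshold, class 1 well above, so synthetic classes are cleanly separable
draw_degradation <- function(label) {
  if (label == 0) {
    degradation_spec(noise_sigma = runif(1, 0, 12),
                     blur_sigma = runif(1, 0, 0.35),
                     zebra_amplitude = 0,
                     ghost_shift = 0, ghost_amplitude = 0)
  } else {
    extra <- sample(c("none", "zebra", "ghost"), 1)
    degradation_spec(noise_sigma = runif(1, 70, 130),
                     blur_sigma = runif(1, 1.6, 2.8),
                     zebra_amplitude = if (extra == "zebra")
                       runif(1, 0.12, 0.3) else 0,
                     zebra_period = sample(6:12, 1),
                     ghost_shift = if (extra == "ghost")
                       sample(8:16, 1) else 0,
                     ghost_amplitude = if (extra == "ghost")
                       runif(1, 0.15, 0.3) else 0)
  }
}

#' Generate a labeled synthetic cohort
#'
#' Balanced cohort of phantom volumes: class-0 (high quality) volumes drawn
#' from a low-severity degradation distribution, class-1 (low quality) from
#' a high-severity one, with a guard band between them. Fully reproducible
#' per seed. Optionally writes NIfTI volumes, a manifest CSV and per-volume
#' spec JSON to a directory.
#'
#' @param n_per_class Patients per class.
#' @param dir Output directory; if `NULL` the volumes stay in memory.
#' @param seed Root seed.
#' @param shape Volume shape passed to [phantom_spec()].
#' @return List with `manifest` (data.frame `patient_id`, `volume_path`,
#'   `label`) and `volumes` (list of `qc_volume`, `NULL` entries when
#'   written to disk only).
#' @export
generate_cohort <- function(n_per_class, dir = NULL, seed = 0L,
                            shape = c(96L, 96L, 20L)) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n_per_class)
  vol_seeds <- seed * 100000L + seq_along(labels)
  degs <- lapply(labels, draw_degradation)
  geom <- data.frame(
    cr = runif(length(labels), 0.52, 0.62),
    ar = runif(length(labels), 0.22, 0.3),
    ac = runif(length(labels), 0.28, 0.36),
    it = runif(length(labels), 3100, 3800))
  volumes <- vector("list", length(labels))
  paths <- character(length(labels))
  ids <- sprintf("P%03d", seq_along(labels))
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (i in seq_along(labels)) {
    sp <- phantom_spec(
      shape = shape,
      ellipse = list(center = c(geom$cr[i], 0.5),
                     axes = c(geom$ar[i], geom$ac[i]),
                     intensity = geom$it[i]),
      degradation = degs[[i]], seed = vol_seeds[i])
    vol <- generate_phantom(sp)
    vol$patient_id <- ids[i]
    if (!is.null(dir)) {
      paths[i] <- file.path(dir, paste0(ids[i], ".nii.gz"))
      img <- RNifti::asNifti(vol$voxels)
      RNifti::pixdim(img) <- c(1, 1, 3)
      RNifti::writeNifti(img, paths[i])
      jsonlite::write_json(
        list(patient_id = ids[i], seed = sp$seed, label = labels[i],
             degradation = unclass(sp$degradation)),
        file.path(dir, paste0(ids[i], ".json")), auto_unbox = TRUE)
    } else {
      volumes[[i]] <- vol
    }
  }
  manifest <- data.frame(patient_id = ids,
                         volume_path = if (is.null(dir)) NA_character_
                                       else paths,
                         label = labels, stringsAsFactors = FALSE)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, volumes = volumes)
}
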