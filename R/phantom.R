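# Run expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stable per-patient substream: md5 of (seed, index), first 7 hex digits
substream_seed <- function(seed, index) {
  strtoi(substr(digest::digest(c(as.integer(seed), as.integer(index))), 1L, 7L),
         base = 16L)
}

#' Specification of a textured lesion phantom
#'
#' Describes a synthetic contrast-enhanced-CT lung lesion: an ellipsoidal
#' soft-tissue lesion (sphere in physical mm) centred in a soft-tissue
#' background, carrying a spatially correlated texture field (white Gaussian
#' noise smoothed to a controllable correlation length and rescaled to a
#' controllable amplitude) plus white acquisition noise.
#'
#' Defaults emulate the study conditions: 1.25 mm reconstructed slices with
#' sub-millimetre in-plane pixels, a 20 mm lesion of mean enhancement 60 HU
#' over a 20 HU soft-tissue surround, texture of 15 HU amplitude at 3 mm
#' correlation length, and 5 HU acquisition noise.
#'
#' @param grid_shape 3D dimensions (slices, rows, columns).
#' @param spacing_mm voxel spacing triple in mm.
#' @param lesion_diameter_mm lesion diameter (sphere in mm).
#' @param background_hu surround intensity.
#' @param lesion_mean_hu mean lesion intensity.
#' @param texture_amplitude_hu standard deviation of the correlated texture.
#' @param texture_scale_mm Gaussian correlation length of the texture.
#' @param noise_sd_hu white acquisition noise SD.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 48L, 48L),
                         spacing_mm = c(1.25, 0.7, 0.7),
                         lesion_diameter_mm = 20,
                         background_hu = 20,
                         lesion_mean_hu = 60,
                         texture_amplitude_hu = 15,
                         texture_scale_mm = 3,
                         noise_sd_hu = 5) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(grid_shape) == 3L, length(spacing_mm) == 3L)
  if (any(grid_shape < 1L)) stop("grid_shape must be positive", call. = FALSE)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive", call. = FALSE)
  if (lesion_diameter_mm <= 0) {
    stop("lesion_diameter_mm must be positive", call. = FALSE)
  }
  if (texture_scale_mm <= 0) stop("texture_scale_mm must be positive", call. = FALSE)
  if (texture_amplitude_hu < 0 || noise_sd_hu < 0) {
    stop("noise amplitudes must be non-negative", call. = FALSE)
  }
  extent <- grid_shape * spacing_mm
  if (any(lesion_diameter_mm > extent)) {
    stop("lesion exceeds the grid extent", call. = FALSE)
  }
  structure(
    list(
      grid_shape = grid_shape, spacing_mm = spacing_mm,
      lesion_diameter_mm = lesion_diameter_mm,
      background_hu = background_hu, lesion_mean_hu = lesion_mean_hu,
      texture_amplitude_hu = texture_amplitude_hu,
      texture_scale_mm = texture_scale_mm, noise_sd_hu = noise_sd_hu
    ),
    class = "phantom_spec"
  )
}

gauss_kernel_1d <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w / sum(w)
}

# separable Gaussian smoothing of a 3D array with reflect boundaries
gauss_smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    w <- gauss_kernel_1d(s)
    h <- (length(w) - 1L) %/% 2L
    out <- array(0, d)
    for (t in seq_along(w)) {
      off <- t - h - 1L
      idx <- reflect_index(seq_len(d[axis]) + off, d[axis])
      shifted <- switch(axis,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE]
      )
      out <- out + w[t] * shifted
    }
    arr <- out
  }
  arr
}

#' Generate a textured lesion phantom
#'
#' Builds the ellipsoidal mask centred in the grid and fills the volume:
#' lesion voxels get `lesion_mean_hu` plus the correlated texture field plus
#' white noise; background voxels get `background_hu` plus white noise. The
#' texture field is white Gaussian noise smoothed to `texture_scale_mm` and
#' rescaled so its grid-wide standard deviation equals
#' `texture_amplitude_hu`. Output is deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec].
#' @param seed integer RNG seed.
#' @param patient_id identifier for the resulting volume.
#' @return list with elements `volume` (a [ct_volume]) and `mask`
#'   (a [lesion_mask]).
#' @export
generate_phantom <- function(spec, seed = 1L, patient_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  centre <- (d + 1) / 2
  r <- spec$lesion_diameter_mm / 2
  # squared physical distance from centre, in mm^2
  dz <- ((seq_len(d[1L]) - centre[1L]) * sp[1L])^2
  dy <- ((seq_len(d[2L]) - centre[2L]) * sp[2L])^2
  dx <- ((seq_len(d[3L]) - centre[3L]) * sp[3L])^2
  dist2 <- outer(outer(dz, dy, `+`), dx, `+`)
  mask_arr <- array(as.numeric(dist2 <= r^2), d)
  if (sum(mask_arr) < 1) {
    stop("lesion too small for the grid resolution", call. = FALSE)
  }

  vox <- with_seed(seed, {
    noise <- array(stats::rnorm(prod(d), 0, 1), d)
    texture <- if (spec$texture_amplitude_hu > 0) {
      f <- gauss_smooth_3d(array(stats::rnorm(prod(d)), d),
                           spec$texture_scale_mm / sp)
      f / stats::sd(f) * spec$texture_amplitude_hu
    } else {
      array(0, d)
    }
    base <- ifelse(mask_arr > 0.5,
                   spec$lesion_mean_hu + texture,
                   spec$background_hu)
    base + spec$noise_sd_hu * noise
  })
  volume <- ct_volume(vox, sp, patient_id)
  list(volume = volume, mask = lesion_mask(mask_arr, volume))
}
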