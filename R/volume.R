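#' CT volume container
#'
#' A 3D grid of CT intensities in Hounsfield Units (HU) together with its
#' physical voxel spacing. Axis order is normalized to slice x row x column,
#' so `voxels[k, , ]` is the k-th axial slice and the in-plane pixel size is
#' `spacing_mm[2:3]`.
#'
#' @param voxels 3D numeric array, axis order slice x row x column, all
#'   values finite.
#' @param spacing_mm numeric triple (slice thickness, row spacing, column
#'   spacing) in millimetres, all strictly positive.
#' @param patient_id opaque identifier string.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, patient_id = "anonymous") {
  voxels <- as_array3d(voxels)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || anyNA(spacing_mm) || any(spacing_mm <= 0)) {
    stop("spacing_mm must be three strictly positive numbers", call. = FALSE)
  }
  if (length(voxels) == 0L) stop("volume grid is empty", call. = FALSE)
  if (!all(is.finite(voxels))) {
    stop("volume intensities must all be finite", call. = FALSE)
  }
  structure(
    list(
      voxels = voxels,
      spacing_mm = spacing_mm,
      patient_id = as.character(patient_id)[1L]
    ),
    class = "ct_volume"
  )
}

#' Binary lesion mask aligned to a CT volume
#'
#' @param voxels 3D array coercible to binary (values > 0.5 are foreground,
#'   tolerating interpolated mask exports); same grid shape as the volume it
#'   refers to.
#' @param reference a [ct_volume] or a grid-shape triple the mask must match.
#' @return An object of class `lesion_mask` with strictly 0/1 voxels.
#' @export
lesion_mask <- function(voxels, reference) {
  voxels <- as_array3d(voxels)
  ref_dim <- if (inherits(reference, "ct_volume")) dim(reference$voxels) else as.integer(reference)
  ref_id <- if (inherits(reference, "ct_volume")) reference$patient_id else NA_character_
  if (!identical(dim(voxels), as.integer(ref_dim))) {
    stop(sprintf(
      "mask shape (%s) does not match reference volume shape (%s)",
      paste(dim(voxels), collapse = "x"), paste(ref_dim, collapse = "x")
    ), call. = FALSE)
  }
  if (!all(is.finite(voxels))) stop("mask values must be finite", call. = FALSE)
  bin <- array(as.numeric(voxels > 0.5), dim = dim(voxels))
  if (sum(bin) < 1) stop("mask has no foreground voxels", call. = FALSE)
  structure(
    list(voxels = bin, reference = ref_id),
    class = "lesion_mask"
  )
}

# Coerce matrices / vectors to a 3D array without copying semantics surprises.
as_array3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(1L, 1L, length(x))
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))
  if (length(dim(x)) != 3L) stop("expected a 3D grid", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf(
    "<ct_volume> %s: %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
    x$patient_id, paste(dim(x$voxels), collapse = "x"),
    paste(format(x$spacing_mm, digits = 3), collapse = " x "),
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "<lesion_mask> %s voxels, %d foreground (ref: %s)\n",
    paste(dim(x$voxels), collapse = "x"), sum(x$voxels), x$reference
  ))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask a [lesion_mask].
#' @return integer count.
#' @export
mask_foreground_count <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  as.integer(sum(mask$voxels))
}
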