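#' Build a Laplacian-of-Gaussian band-pass kernel for one spatial scale
#'
#' The spatial scale filter (SSF) value is interpreted as the approximate
#' diameter in mm of the structures the filter highlights. The LoG blob
#' response is maximal for a blob of radius \eqn{r = \sigma\sqrt{2}}, so the
#' default convention maps \eqn{\sigma_{mm} = SSF / (2\sqrt{2})}. `ssf_mm = 0`
#' means no filtration and returns an identity marker.
#'
#' Coefficients are the sign-inverted, scale-normalised LoG
#' \deqn{w(u, v) \propto \frac{1}{\sigma^2}
#'       \left(1 - \frac{r^2}{2\sigma^2}\right) e^{-r^2 / 2\sigma^2}, \quad
#'       r^2 = u^2 + v^2 \text{ in mm}^2,}
#' sampled on a square support of half-width `ceil(4 * max(sigma_px))` pixels
#' and then mean-subtracted so they sum to exactly zero: a uniform region
#' filters to zero and bright structures near the scale give positive
#' responses. Pixel anisotropy is handled by sampling in physical mm, and the
#' \eqn{1/\sigma^2} scale normalisation (with the pixel area folded in) makes
#' response magnitudes comparable across scales and across resamplings of the
#' same anatomy.
#'
#' @param ssf_mm spatial scale in mm; 0 (identity) or positive (2-6 in a
#'   standard run).
#' @param in_plane_spacing_mm pixel size pair (row, column) in mm.
#' @param sigma_per_ssf multiplier mapping SSF to sigma in mm
#'   (default `1 / (2 * sqrt(2))`); exposed because the mapping used by
#'   proprietary implementations is unpublished.
#' @return An object of class `log_kernel` with fields `ssf_mm`, `sigma_px`
#'   (per in-plane axis), and `coefficients` (a matrix; `NULL` for the
#'   identity kernel).
#' @export
build_log_kernel <- function(ssf_mm, in_plane_spacing_mm,
                             sigma_per_ssf = 1 / (2 * sqrt(2))) {
  spacing <- as.numeric(in_plane_spacing_mm)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || anyNA(spacing) || any(spacing <= 0)) {
    stop("in-plane spacing must be two strictly positive numbers", call. = FALSE)
  }
  ssf_mm <- as.numeric(ssf_mm)[1L]
  if (is.na(ssf_mm) || ssf_mm < 0) stop("ssf_mm must be >= 0", call. = FALSE)
  if (ssf_mm == 0) {
    return(structure(
      list(ssf_mm = 0, sigma_px = c(0, 0), coefficients = NULL),
      class = "log_kernel"
    ))
  }
  sigma_mm <- ssf_mm * sigma_per_ssf
  sigma_px <- sigma_mm / spacing
  half <- as.integer(ceiling(4 * max(sigma_px)))
  # physical offsets of each tap, in mm
  u <- (-half:half) * spacing[1L]
  v <- (-half:half) * spacing[2L]
  r2 <- outer(u^2, v^2, `+`)
  w <- (1 - r2 / (2 * sigma_mm^2)) * exp(-r2 / (2 * sigma_mm^2))
  # scale normalisation: the discrete sum then approximates the continuous
  # scale-normalised LoG response, so (a) a Gaussian blob of matched size
  # gives the maximal response over scales and (b) responses are invariant
  # to the pixel size the slice happens to be sampled at
  w <- w * prod(spacing) / sigma_mm^2
  w <- w - mean(w) # exact zero sum: DC is fully rejected
  structure(
    list(ssf_mm = ssf_mm, sigma_px = sigma_px, coefficients = w),
    class = "log_kernel"
  )
}

#' @export
print.log_kernel <- function(x, ...) {
  if (is.null(x$coefficients)) {
    cat("<log_kernel> SSF 0 (identity, no filtration)\n")
  } else {
    cat(sprintf(
      "<log_kernel> SSF %g mm, sigma %s px, support %dx%d\n",
      x$ssf_mm, paste(format(x$sigma_px, digits = 4), collapse = " x "),
      nrow(x$coefficients), ncol(x$coefficients)
    ))
  }
  invisible(x)
}

# Reflect (mirror-without-edge-repeat is NOT used; scipy-style 'reflect',
# i.e. d c b a | a b c d) index mapping, folding as often as needed so pads
# wider than the image remain valid.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  j <- (idx - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  ifelse(j < n, j + 1L, period - j)
}

pad_reflect <- function(x, h) {
  ri <- reflect_index((1L - h):(nrow(x) + h), nrow(x))
  ci <- reflect_index((1L - h):(ncol(x) + h), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' Filter one axial slice with a LoG kernel
#'
#' 2D correlation with reflect boundary padding; the output has the shape of
#' the input. The identity kernel (SSF 0) returns the input unchanged. The
#' correlation is evaluated through FFTs on the reflect-padded slice, which
#' is exact (to round-off) and fast for the coarse-scale kernels.
#'
#' @param slice 2D numeric matrix of intensities (finite).
#' @param kernel a [build_log_kernel] result.
#' @return filtered matrix, same shape as `slice`.
#' @export
filter_slice <- function(slice, kernel) {
  stopifnot(inherits(kernel, "log_kernel"))
  slice <- as.matrix(slice)
  if (!all(is.finite(slice))) {
    stop("slice contains non-finite values", call. = FALSE)
  }
  if (is.null(kernel$coefficients)) return(slice)
  k <- kernel$coefficients
  h <- (nrow(k) - 1L) %/% 2L
  p <- pad_reflect(slice, h)
  np <- nrow(p); mp <- ncol(p)
  fk <- kernel_fft(kernel, np, mp)
  out <- Re(stats::fft(stats::fft(p) * fk, inverse = TRUE)) / (np * mp)
  out[(h + 1L):(h + nrow(slice)), (h + 1L):(h + ncol(slice)), drop = FALSE]
}

# Cached FFT of a kernel embedded at a given padded size: every slice of a
# volume reuses the same transform. The kernel is embedded for circular
# *correlation*: tap (a, b), a,b in -h..h, goes to index (-a mod np,
# -b mod mp) of the convolution kernel rotated 180 degrees; equivalently
# rot180(k) with its centre wrapped to (1, 1).
.kernel_fft_cache <- new.env(parent = emptyenv())

kernel_fft <- function(kernel, np, mp) {
  key <- paste(kernel$ssf_mm, paste(signif(kernel$sigma_px, 12), collapse = ","),
               np, mp, sep = "|")
  hit <- .kernel_fft_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- kernel$coefficients
  h <- (nrow(k) - 1L) %/% 2L
  kr <- k[nrow(k):1L, ncol(k):1L, drop = FALSE]
  kp <- matrix(0, np, mp)
  kp[((-h):(h)) %% np + 1L, ((-h):(h)) %% mp + 1L] <- kr
  fk <- stats::fft(kp)
  if (length(ls(.kernel_fft_cache)) > 64L) {
    rm(list = ls(.kernel_fft_cache), envir = .kernel_fft_cache)
  }
  .kernel_fft_cache[[key]] <- fk
  fk
}

#' Pool filtered intensities over the lesion VOI at one scale
#'
#' Every axial slice that intersects the mask is filtered whole (the full
#' slice, so mask edges see genuine image context rather than a cropped
#' border) and the filtered values are then sampled inside the mask. Values
#' from all slices are pooled into a single volumetric sample; at SSF 0 the
#' raw HU values are pooled unfiltered.
#'
#' @param volume a [ct_volume].
#' @param mask a [lesion_mask] congruent with `volume`.
#' @param ssf_mm one spatial scale in mm.
#' @param sigma_per_ssf see [build_log_kernel].
#' @return list of class `voi_sample` with `values`, `ssf_mm`, `n`.
#' @export
extract_voi_values <- function(volume, mask, ssf_mm,
                               sigma_per_ssf = 1 / (2 * sqrt(2))) {
  values <- unlist(extract_voi_slices(volume, mask, ssf_mm, sigma_per_ssf),
                   use.names = FALSE)
  structure(
    list(values = values, ssf_mm = as.numeric(ssf_mm)[1L], n = length(values)),
    class = "voi_sample"
  )
}

# per-slice filtered VOI values: a list with one numeric vector per axial
# slice intersecting the mask
extract_voi_slices <- function(volume, mask, ssf_mm,
                               sigma_per_ssf = 1 / (2 * sqrt(2))) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lesion_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels))) {
    stop("mask is not congruent with volume", call. = FALSE)
  }
  kernel <- build_log_kernel(ssf_mm, volume$spacing_mm[2:3], sigma_per_ssf)
  slices <- which(apply(mask$voxels, 1L, sum) > 0)
  out <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    k <- slices[i]
    sl <- volume$voxels[k, , , drop = TRUE]
    msk <- mask$voxels[k, , , drop = TRUE] > 0.5
    f <- filter_slice(sl, kernel)
    out[[i]] <- f[msk]
  }
  names(out) <- slices
  out
}
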