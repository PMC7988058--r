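FEATURE_NAMES <- c("mean", "sd", "entropy", "kurtosis", "skewness", "mpp")

#' Six first-order histogram features of a VOI sample
#'
#' Computes the filtration-histogram feature set on the pooled intensities of
#' one VOI at one spatial scale:
#' \itemize{
#'   \item `mean` — arithmetic mean.
#'   \item `sd` — sample standard deviation (n-1 denominator; 0 for n = 1).
#'   \item `entropy` — Shannon entropy in bits of the normalised histogram
#'     with `entropy_bins` equal-width bins spanning the sample's own
#'     \[min, max\] (0 when all values are equal).
#'   \item `kurtosis` — excess kurtosis \eqn{m_4 / m_2^2 - 3} (normal = 0).
#'   \item `skewness` — \eqn{m_3 / m_2^{3/2}} (biased moment ratios).
#'   \item `mpp` — mean of strictly positive values ("mean of positive
#'     pixels"); `NA` when no positive values exist.
#' }
#' Shape moments (`skewness`, `kurtosis`) are `NA` on zero-variance samples
#' rather than infinite; undefined features are always explicit `NA`, never 0.
#'
#' @param sample a `voi_sample` from [extract_voi_values], or a bare numeric
#'   vector of intensities.
#' @param entropy_bins number of equal-width histogram bins (default 256).
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return named numeric vector of the six features plus `n` and `ssf`.
#' @export
compute_features <- function(sample, entropy_bins = 256L,
                             sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  ssf <- NA_real_
  if (inherits(sample, "voi_sample")) {
    ssf <- sample$ssf_mm
    x <- sample$values
  } else {
    x <- as.numeric(sample)
  }
  n <- length(x)
  if (n < 1L) stop("empty sample", call. = FALSE)
  if (!all(is.finite(x))) stop("sample contains non-finite values", call. = FALSE)

  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  s <- if (n == 1L) {
    0
  } else if (sd_denominator == "n-1") {
    sqrt(m2 * n / (n - 1))
  } else {
    sqrt(m2)
  }
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  ent <- shannon_entropy_bits(x, entropy_bins)
  pos <- x[x > 0]
  mpp <- if (length(pos)) mean(pos) else NA_real_

  c(mean = mu, sd = s, entropy = ent, kurtosis = kurt, skewness = skew,
    mpp = mpp, n = n, ssf = ssf)
}

# Histogram entropy, base 2, over [min, max] of the sample itself.
shannon_entropy_bits <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0)
  idx <- pmin(as.integer(floor((x - lo) / (hi - lo) * bins)) + 1L, bins)
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the full filtration-histogram feature table for one lesion
#'
#' Runs [extract_voi_values] and [compute_features] at every requested
#' spatial scale. The standard run uses SSF 0 (unfiltered) plus 2-6 mm,
#' giving 6 scales x 6 features = 36 values per lesion.
#'
#' @param volume a [ct_volume].
#' @param mask a [lesion_mask] congruent with `volume`.
#' @param ssf_list scales in mm (default `c(0, 2, 3, 4, 5, 6)`).
#' @param pooling `"volumetric"` (default) pools the filtered voxels of all
#'   slices into one histogram per scale; `"slice_mean"` computes the six
#'   features per axial slice and averages them across slices (offered
#'   because proprietary implementations do not document which unit they
#'   use; no fidelity to any of them is claimed for this mode).
#' @param entropy_bins,sd_denominator,sigma_per_ssf configuration knobs; see
#'   [compute_features] and [build_log_kernel].
#' @return A `feature_table` data frame with columns `patient_id`, `ssf`,
#'   and the six feature columns, one row per scale.
#' @export
extract_feature_table <- function(volume, mask, ssf_list = c(0, 2, 3, 4, 5, 6),
                                  pooling = c("volumetric", "slice_mean"),
                                  entropy_bins = 256L,
                                  sd_denominator = "n-1",
                                  sigma_per_ssf = 1 / (2 * sqrt(2))) {
  pooling <- match.arg(pooling)
  rows <- lapply(ssf_list, function(ssf) {
    fv <- if (pooling == "volumetric") {
      sample <- extract_voi_values(volume, mask, ssf, sigma_per_ssf)
      compute_features(sample, entropy_bins, sd_denominator)
    } else {
      per <- extract_voi_slices(volume, mask, ssf, sigma_per_ssf)
      mat <- vapply(per, function(v) {
        compute_features(v, entropy_bins, sd_denominator)[FEATURE_NAMES]
      }, numeric(length(FEATURE_NAMES)))
      # average defined values across slices; all-missing stays missing
      apply(mat, 1L, function(r) {
        if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
      })
    }
    data.frame(
      patient_id = volume$patient_id, ssf = ssf,
      mean = fv[["mean"]], sd = fv[["sd"]], entropy = fv[["entropy"]],
      kurtosis = fv[["kurtosis"]], skewness = fv[["skewness"]],
      mpp = fv[["mpp"]], stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Validate a feature table's shape
#'
#' @param table data frame with columns `patient_id`, `ssf` and the six
#'   feature columns.
#' @return the table, invisibly, with class `feature_table`.
#' @export
as_feature_table <- function(table) {
  needed <- c("patient_id", "ssf", FEATURE_NAMES)
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  table <- as.data.frame(table)[needed]
  if (anyDuplicated(table[c("patient_id", "ssf")])) {
    stop("duplicate (patient_id, ssf) rows in feature table", call. = FALSE)
  }
  class(table) <- c("feature_table", "data.frame")
  table
}
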