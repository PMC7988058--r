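#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI files (`.nii` / `.nii.gz`) are read through RNifti; a directory is
#' treated as one DICOM series (single-frame CT slices, little-endian,
#' uncompressed). Axis order is normalised to slice x row x column and DICOM
#' stored values are converted to HU with the rescale slope/intercept.
#' Spacing always comes from the header; absent spacing metadata is an
#' error, never a silent default.
#'
#' @param path NIfTI file or DICOM series directory.
#' @param patient_id identifier to attach; defaults to the file/directory
#'   name (for DICOM, the PatientID tag when present).
#' @return a [ct_volume].
#' @export
read_volume <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (dir.exists(path)) {
    return(read_dicom_series(path, patient_id = patient_id))
  }
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI image", call. = FALSE)
  if (length(pix) < 3L || anyNA(pix[1:3]) || any(pix[1:3] <= 0)) {
    stop("NIfTI header lacks valid voxel spacing", call. = FALSE)
  }
  # NIfTI stores x (column) fastest, then y (row), then z (slice)
  vox <- aperm(arr, c(3L, 2L, 1L))
  if (is.null(patient_id)) {
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  ct_volume(vox, spacing_mm = c(pix[3L], pix[2L], pix[1L]),
            patient_id = patient_id)
}

#' Write a CT volume (or mask grid) to NIfTI
#'
#' @param volume a [ct_volume], or a [lesion_mask] written on the geometry of
#'   `reference`.
#' @param path output `.nii` or `.nii.gz` path.
#' @param reference for masks, the [ct_volume] supplying the spacing.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, reference = NULL) {
  if (inherits(volume, "lesion_mask")) {
    stopifnot(inherits(reference, "ct_volume"))
    vox <- volume$voxels
    spacing <- reference$spacing_mm
  } else {
    stopifnot(inherits(volume, "ct_volume"))
    vox <- volume$voxels
    spacing <- volume$spacing_mm
  }
  arr <- aperm(vox, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing[3L], spacing[2L], spacing[1L])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a lesion mask aligned to a reference volume
#'
#' @param path NIfTI mask file (values > 0.5 become foreground).
#' @param reference the [ct_volume] the mask must be congruent with.
#' @return a [lesion_mask].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "ct_volume"))
  m <- read_volume(path, patient_id = reference$patient_id)
  lesion_mask(m$voxels, reference)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1L))
  out
}

#' Write a feature table as CSV
#'
#' Header `patient_id,ssf,mean,sd,entropy,kurtosis,skewness,mpp`; missing
#' values are emitted as empty fields; numbers carry full precision so a
#' read-back reproduces the table.
#'
#' @param table a `feature_table` (see [extract_feature_table]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- as_feature_table(table)
  out <- data.frame(
    patient_id = as.character(table$patient_id),
    ssf = fmt_num(table$ssf),
    stringsAsFactors = FALSE
  )
  for (f in FEATURE_NAMES) out[[f]] <- fmt_num(table[[f]])
  utils::write.table(out, path, sep = ",", na = "", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a feature table CSV written by [write_feature_table]
#' @param path CSV path.
#' @return a `feature_table` data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tab$patient_id <- as.character(tab$patient_id)
  as_feature_table(tab)
}

#' Read a per-patient survival table
#'
#' Expected CSV columns: `patient_id`, `os_days`, `os_event`, `pfs_days`,
#' `pfs_event`, `progressor`. Times are days from first drug administration;
#' event flags are 0/1 (1 = death / progression); `progressor` is the binary
#' response-assessment label consumed by the ROC screen.
#'
#' @param path CSV path.
#' @return validated data frame of class `survival_table`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_survival_table(tab)
}

#' Validate a survival table
#' @param tab data frame with the survival columns.
#' @return the validated table with class `survival_table`.
#' @export
as_survival_table <- function(tab) {
  needed <- c("patient_id", "os_days", "os_event", "pfs_days", "pfs_event",
              "progressor")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("survival table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- as.data.frame(tab)
  tab$patient_id <- as.character(tab$patient_id)
  for (cc in c("os_days", "pfs_days")) {
    if (any(!is.finite(tab[[cc]])) || any(tab[[cc]] < 0)) {
      stop(cc, " must be non-negative and finite", call. = FALSE)
    }
  }
  for (cc in c("os_event", "pfs_event", "progressor")) {
    if (!all(tab[[cc]] %in% c(0, 1))) {
      stop(cc, " must be binary 0/1", call. = FALSE)
    }
  }
  bad <- tab$os_event == 1 & tab$pfs_event == 1 & tab$pfs_days > tab$os_days
  if (any(bad)) {
    stop("pfs_days exceeds os_days for observed events: ",
         paste(tab$patient_id[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$patient_id)) {
    stop("duplicate patient_id in survival table", call. = FALSE)
  }
  class(tab) <- c("survival_table", "data.frame")
  tab
}

#' Write a survival table as CSV
#' @param tab a `survival_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(tab, path) {
  tab <- as_survival_table(tab)
  utils::write.table(as.data.frame(tab), path, sep = ",", na = "",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
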