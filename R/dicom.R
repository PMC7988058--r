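# Minimal DICOM support for single-frame CT series: uncompressed
# little-endian transfer syntaxes only (implicit 1.2.840.10008.1.2 and
# explicit 1.2.840.10008.1.2.1). Covers what a CT texture pipeline needs --
# geometry, rescale to HU, series identity -- not the general standard.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"

u16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}
u32 <- function(raw, pos) {
  lo <- u16(raw, pos)
  hi <- u16(raw, pos + 2L)
  hi * 65536 + lo
}

tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

# VRs with the 2-byte-reserved / 4-byte-length explicit encoding
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Skip an undefined-length sequence; returns position after the
# SequenceDelimitationItem. Items themselves may be undefined length.
skip_undefined <- function(raw, pos) {
  repeat {
    if (pos + 7L > length(raw)) stop("truncated DICOM sequence", call. = FALSE)
    g <- u16(raw, pos); e <- u16(raw, pos + 2L); len <- u32(raw, pos + 4L)
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE0DD) return(pos) # sequence delimiter
    if (g == 0xFFFE && e == 0xE000) { # item
      if (len == 4294967295) pos <- skip_undefined_item(raw, pos)
      else pos <- pos + len
    } else {
      stop("malformed DICOM sequence", call. = FALSE)
    }
  }
}

skip_undefined_item <- function(raw, pos) {
  repeat {
    g <- u16(raw, pos); e <- u16(raw, pos + 2L); len <- u32(raw, pos + 4L)
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE00D) return(pos) # item delimiter
    if (len == 4294967295) pos <- skip_undefined(raw, pos)
    else pos <- pos + len
  }
}

parse_elements <- function(raw, pos, explicit, stop_group = NULL) {
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n + 1L && pos <= n) {
    if (pos + 7L > n) break
    group <- u16(raw, pos)
    elem <- u16(raw, pos + 2L)
    if (!is.null(stop_group) && group != stop_group) break
    if (explicit && group != 0xFFFE) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- u16(raw, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(raw, pos + 4L)
      hdr <- 8L
    }
    body <- pos + hdr
    if (len == 4294967295) { # undefined length (sequence / encapsulated)
      pos <- skip_undefined(raw, body)
      next
    }
    if (body + len - 1L > n) stop("truncated DICOM element", call. = FALSE)
    value <- if (len > 0L) raw[body:(body + len - 1L)] else raw(0L)
    out[[tag_key(group, elem)]] <- list(vr = vr, value = value)
    pos <- body + len
  }
  list(elements = out, pos = pos)
}

dicom_string <- function(el) {
  if (is.null(el)) return(NA_character_)
  s <- rawToChar(el$value[el$value != as.raw(0L)])
  trimws(s)
}

dicom_numeric <- function(el) {
  s <- dicom_string(el)
  if (is.na(s) || !nzchar(s)) return(numeric(0L))
  as.numeric(strsplit(s, "\\\\")[[1L]])
}

dicom_us <- function(el) {
  if (is.null(el) || length(el$value) < 2L) return(NA_integer_)
  u16(el$value, 1L)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM file: ", path, call. = FALSE)
  }
  meta <- parse_elements(raw, 133L, explicit = TRUE, stop_group = 0x0002)
  ts <- dicom_string(meta$elements[["0002,0010"]])
  explicit <- if (is.na(ts) || ts == UID_EXPLICIT_LE) {
    TRUE
  } else if (ts == UID_IMPLICIT_LE) {
    FALSE
  } else {
    stop("unsupported DICOM transfer syntax ", ts, " in ", path, call. = FALSE)
  }
  ds <- parse_elements(raw, meta$pos, explicit = explicit)$elements

  rows <- dicom_us(ds[["0028,0010"]])
  cols <- dicom_us(ds[["0028,0011"]])
  bits <- dicom_us(ds[["0028,0100"]])
  signed <- identical(dicom_us(ds[["0028,0103"]]), 1L)
  px <- ds[["7FE0,0010"]]
  if (is.na(rows) || is.na(cols) || is.null(px)) {
    stop("DICOM file lacks image data: ", path, call. = FALSE)
  }
  if (!identical(bits, 16L)) {
    stop("only 16-bit DICOM pixel data is supported: ", path, call. = FALSE)
  }
  stored <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                    endian = "little", signed = signed)
  slope <- dicom_numeric(ds[["0028,1053"]])
  intercept <- dicom_numeric(ds[["0028,1052"]])
  if (!length(slope)) slope <- 1
  if (!length(intercept)) intercept <- 0
  hu <- matrix(stored * slope[1L] + intercept[1L], nrow = rows, ncol = cols,
               byrow = TRUE) # PixelData is row-major

  spacing <- dicom_numeric(ds[["0028,0030"]]) # (row, column)
  if (length(spacing) != 2L || anyNA(spacing) || any(spacing <= 0)) {
    stop("DICOM file lacks PixelSpacing metadata: ", path, call. = FALSE)
  }
  ipp <- dicom_numeric(ds[["0020,0032"]])
  list(
    pixels = hu,
    pixel_spacing = spacing,
    slice_thickness = dicom_numeric(ds[["0018,0050"]]),
    position_z = if (length(ipp) == 3L) ipp[3L] else NA_real_,
    instance = dicom_numeric(ds[["0020,0013"]]),
    series_uid = dicom_string(ds[["0020,000E"]]),
    patient_id = dicom_string(ds[["0010,0020"]])
  )
}

read_dicom_series <- function(dir, patient_id = NULL) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("empty DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, read_dicom_file)

  uids <- unique(vapply(slices, `[[`, character(1L), "series_uid"))
  uids <- uids[!is.na(uids)]
  if (length(uids) > 1L) {
    stop("directory mixes multiple DICOM series UIDs: ",
         paste(uids, collapse = ", "), call. = FALSE)
  }
  z <- vapply(slices, `[[`, numeric(1L), "position_z")
  ord <- if (!anyNA(z)) {
    order(z)
  } else {
    inst <- vapply(slices, function(s) {
      if (length(s$instance)) s$instance[1L] else NA_real_
    }, numeric(1L))
    if (anyNA(inst)) stop("DICOM series lacks slice ordering metadata",
                          call. = FALSE)
    order(inst)
  }
  slices <- slices[ord]
  z <- z[ord]

  sp <- slices[[1L]]$pixel_spacing
  shapes <- vapply(slices, function(s) paste(dim(s$pixels), collapse = "x"),
                   character(1L))
  if (length(unique(shapes)) != 1L) {
    stop("DICOM slices have inconsistent shapes", call. = FALSE)
  }
  dz <- if (length(slices) > 1L && !anyNA(z)) {
    d <- diff(z)
    if (max(abs(d - d[1L])) > 1e-4) {
      stop("non-uniform DICOM slice positions", call. = FALSE)
    }
    abs(d[1L])
  } else if (length(st <- slices[[1L]]$slice_thickness)) {
    st[1L]
  } else {
    stop("DICOM series lacks slice-spacing metadata", call. = FALSE)
  }

  vox <- array(0, dim = c(length(slices), nrow(slices[[1L]]$pixels),
                          ncol(slices[[1L]]$pixels)))
  for (k in seq_along(slices)) vox[k, , ] <- slices[[k]]$pixels
  if (is.null(patient_id)) {
    pid <- slices[[1L]]$patient_id
    patient_id <- if (!is.na(pid) && nzchar(pid)) pid else basename(dir)
  }
  ct_volume(vox, spacing_mm = c(dz, sp[1L], sp[2L]), patient_id = patient_id)
}

# ---- writing (used for round-trip fixtures and export) ----------------------

enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
enc_u32 <- function(x) {
  x <- as.numeric(x)
  c(enc_u16(x %% 65536), enc_u16(x %/% 65536))
}

pad_even <- function(v, pad = as.raw(0x20)) {
  if (length(v) %% 2L == 1L) c(v, pad) else v
}

enc_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    value <- pad_even(value, if (vr == "UI") as.raw(0L) else as.raw(0x20))
  }
  hdr <- c(enc_u16(group), enc_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), enc_u32(length(value)), value)
  } else {
    c(hdr, enc_u16(length(value)), value)
  }
}

filtrad_uid <- function(...) {
  # deterministic study/series/instance UIDs under a private-style root
  h <- digest::digest(list(...), algo = "md5")
  paste0("1.2.826.0.1.3680043.9.9999.",
         strtoi(substr(h, 1, 7), 16L), ".", strtoi(substr(h, 8, 14), 16L))
}

#' Write a CT volume as a single-series DICOM directory
#'
#' One explicit-VR little-endian file per axial slice, 16-bit signed stored
#' values with rescale intercept -1024 (slope 1), standard CT geometry tags
#' (PixelSpacing, ImagePositionPatient, SliceThickness). Intended for
#' round-trip fixtures and interoperability checks; HU values are rounded to
#' integers as in real CT storage.
#'
#' @param volume a [ct_volume].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume$voxels)
  sp <- volume$spacing_mm
  series_uid <- filtrad_uid(volume$patient_id, d, sp, "series")
  study_uid <- filtrad_uid(volume$patient_id, "study")
  intercept <- -1024
  for (k in seq_len(d[1L])) {
    sl <- volume$voxels[k, , , drop = TRUE]
    stored <- round(sl) - intercept
    if (any(stored < -32768 | stored > 32767)) {
      stop("HU values out of 16-bit storage range", call. = FALSE)
    }
    # row-major pixel order
    px <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
    sop_uid <- filtrad_uid(series_uid, k)
    ds <- c(
      enc_elem(0x0008, 0x0016, "UI", UID_CT_STORAGE),
      enc_elem(0x0008, 0x0018, "UI", sop_uid),
      enc_elem(0x0008, 0x0060, "CS", "CT"),
      enc_elem(0x0010, 0x0020, "LO", volume$patient_id),
      enc_elem(0x0018, 0x0050, "DS", sprintf("%g", sp[1L])),
      enc_elem(0x0020, 0x000D, "UI", study_uid),
      enc_elem(0x0020, 0x000E, "UI", series_uid),
      enc_elem(0x0020, 0x0013, "IS", sprintf("%d", k)),
      enc_elem(0x0020, 0x0032, "DS",
               sprintf("0\\0\\%g", (k - 1L) * sp[1L])),
      enc_elem(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      enc_elem(0x0028, 0x0002, "US", enc_u16(1L)),
      enc_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
      enc_elem(0x0028, 0x0010, "US", enc_u16(d[2L])),
      enc_elem(0x0028, 0x0011, "US", enc_u16(d[3L])),
      enc_elem(0x0028, 0x0030, "DS", sprintf("%g\\%g", sp[2L], sp[3L])),
      enc_elem(0x0028, 0x0100, "US", enc_u16(16L)),
      enc_elem(0x0028, 0x0101, "US", enc_u16(16L)),
      enc_elem(0x0028, 0x0102, "US", enc_u16(15L)),
      enc_elem(0x0028, 0x0103, "US", enc_u16(1L)),
      enc_elem(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
      enc_elem(0x0028, 0x1053, "DS", "1"),
      enc_elem(0x7FE0, 0x0010, "OW", px)
    )
    meta_body <- c(
      enc_elem(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      enc_elem(0x0002, 0x0002, "UI", UID_CT_STORAGE),
      enc_elem(0x0002, 0x0003, "UI", sop_uid),
      enc_elem(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
      enc_elem(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.9999.1")
    )
    meta <- c(enc_elem(0x0002, 0x0000, "UL", enc_u32(length(meta_body))),
              meta_body)
    out <- c(raw(128L), charToRaw("DICM"), meta, ds)
    writeBin(out, file.path(dir, sprintf("slice_%04d.dcm", k)))
  }
  invisible(dir)
}
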