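test_that("volume and mask containers enforce their invariants", {
  expect_error(ct_volume(array(1, c(2, 2, 2)), c(1, 0, 1)), "positive")
  expect_error(ct_volume(array(c(1, NaN), c(1, 1, 2)), c(1, 1, 1)), "finite")
  v <- ct_volume(array(0, c(2, 3, 4)), c(1.25, 0.7, 0.7), "p1")
  expect_error(lesion_mask(array(0, c(2, 3, 4)), v), "no foreground")

  # binarization at 0.5 tolerates interpolated exports
  m <- array(0, c(2, 3, 4)); m[1, 2, 2] <- 0.9; m[2, 1, 1] <- 0.4
  lm <- lesion_mask(m, v)
  expect_equal(mask_foreground_count(lm), 1L)
  expect_true(all(lm$voxels %in% c(0, 1)))

  allones <- lesion_mask(array(1, c(2, 3, 4)), v)
  expect_equal(mask_foreground_count(allones), 24L)
})

test_that("NIfTI round trip preserves voxels, spacing and axis order", {
  ph <- tiny_phantom(seed = 11, id = "rt")
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, tmp)
  back <- read_volume(tmp, patient_id = "rt")
  expect_equal(back$voxels, ph$volume$voxels, tolerance = 1e-6)
  expect_equal(back$spacing_mm, ph$volume$spacing_mm, tolerance = 1e-6)

  mtmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$mask, mtmp, reference = ph$volume)
  mback <- read_mask(mtmp, back)
  expect_identical(mback$voxels, ph$mask$voxels)

  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such")
})

test_that("DICOM round trip and rescale arithmetic are exact", {
  set.seed(4)
  vox <- round(array(rnorm(5 * 12 * 10, 30, 40), c(5, 12, 10)))
  v <- ct_volume(vox, c(1.25, 0.7, 0.8), "dcmpat")
  dir <- withr::local_tempdir()
  write_dicom_series(v, dir)
  back <- read_volume(dir)
  expect_equal(back$voxels, v$voxels, tolerance = 1e-9)
  expect_equal(back$spacing_mm, v$spacing_mm, tolerance = 1e-9)
  expect_identical(back$patient_id, "dcmpat")

  # stored value 1024 with intercept -1024 decodes to 0 HU
  files <- list.files(dir, full.names = TRUE)
  one <- filtrad:::read_dicom_file(files[1])
  zero <- ct_volume(array(0, c(1, 4, 4)), c(1, 1, 1), "z")
  zdir <- withr::local_tempdir()
  write_dicom_series(zero, zdir)
  zslice <- filtrad:::read_dicom_file(list.files(zdir, full.names = TRUE)[1])
  expect_true(all(zslice$pixels == 0))
  expect_equal(one$pixel_spacing, c(0.7, 0.8))
})

test_that("NIfTI and DICOM encodings of one phantom read back identically", {
  ph <- generate_phantom(
    phantom_spec(grid_shape = c(6L, 20L, 20L), spacing_mm = c(2.5, 1, 1),
                 lesion_diameter_mm = 10),
    seed = 3, patient_id = "xenc"
  )
  # integer HU so the 16-bit DICOM storage is lossless
  vol <- ct_volume(round(ph$volume$voxels), ph$volume$spacing_mm, "xenc")
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  dcm <- withr::local_tempdir()
  write_volume(vol, nii)
  write_dicom_series(vol, dcm)
  v1 <- read_volume(nii)
  v2 <- read_volume(dcm)
  expect_lt(max(abs(v1$voxels - v2$voxels)), 1e-6)
  expect_equal(v1$spacing_mm, v2$spacing_mm, tolerance = 1e-6)
})

test_that("mixed series UIDs in one directory are rejected", {
  a <- ct_volume(array(1, c(2, 4, 4)), c(1, 1, 1), "a")
  b <- ct_volume(array(2, c(2, 4, 4)), c(1, 1, 1), "b")
  dir <- withr::local_tempdir()
  write_dicom_series(a, dir)
  tmp <- withr::local_tempdir()
  write_dicom_series(b, tmp)
  file.copy(list.files(tmp, full.names = TRUE)[1],
            file.path(dir, "intruder.dcm"))
  expect_error(read_volume(dir), "mixes multiple DICOM series")
})

test_that("our DICOM reader agrees with an independently written series", {
  # pydicom writes the series; only our reader touches it afterwards
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  dir <- withr::local_tempdir()
  script <- sprintf('
import numpy as np, pydicom, os
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
rng = np.random.default_rng(12)
arr = rng.integers(-200, 300, size=(3, 8, 6)).astype(np.int16)
series = generate_uid(); study = generate_uid()
os.makedirs(r"%s", exist_ok=True)
for k in range(arr.shape[0]):
    ds = Dataset()
    ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
    ds.SOPInstanceUID = generate_uid()
    ds.Modality = "CT"; ds.PatientID = "pypat"
    ds.StudyInstanceUID = study; ds.SeriesInstanceUID = series
    ds.InstanceNumber = k + 1
    ds.ImagePositionPatient = [0, 0, 2.0 * k]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.SliceThickness = 2.0
    ds.SamplesPerPixel = 1; ds.PhotometricInterpretation = "MONOCHROME2"
    ds.Rows, ds.Columns = arr.shape[1:]
    ds.PixelSpacing = [0.9, 1.1]
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.RescaleIntercept = "-1024"; ds.RescaleSlope = "1"
    ds.PixelData = (arr[k] + 1024).astype(np.int16).tobytes()
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = ds.SOPClassUID
    meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta = meta
    ds.save_as(os.path.join(r"%s", f"s{k}.dcm"), enforce_file_format=True)
np.savetxt(os.path.join(r"%s", "truth.txt"), arr.reshape(3, -1), fmt="%%d")
', dir, dir, dir)
  res <- system2(py, "-", input = script, stdout = TRUE, stderr = TRUE)
  truth_file <- file.path(dir, "truth.txt")
  skip_if(!file.exists(truth_file),
          paste("pydicom unavailable:", paste(res, collapse = " ")))
  truth <- as.matrix(utils::read.table(truth_file))
  file.remove(truth_file)
  v <- read_volume(dir)
  expect_identical(dim(v$voxels), c(3L, 8L, 6L))
  expect_equal(v$spacing_mm, c(2.0, 0.9, 1.1), tolerance = 1e-9)
  expect_identical(v$patient_id, "pypat")
  for (k in 1:3) {
    want <- matrix(truth[k, ], nrow = 8, byrow = TRUE)
    expect_equal(v$voxels[k, , ], want, ignore_attr = TRUE)
  }
})

test_that("feature table CSV round-trips exactly, missing values as blanks", {
  ph <- tiny_phantom(seed = 6)
  tab <- extract_feature_table(ph$volume, ph$mask)
  tab$mpp[2] <- NA # force an explicit missing cell
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, tmp)
  lines <- readLines(tmp)
  expect_identical(lines[1],
                   "patient_id,ssf,mean,sd,entropy,kurtosis,skewness,mpp")
  expect_match(lines[3], ",$") # trailing empty field for the missing mpp
  back <- read_feature_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab),
               tolerance = 1e-12, ignore_attr = TRUE)

  empty <- tab[0, ]
  write_feature_table(empty, tmp)
  expect_identical(readLines(tmp),
                   "patient_id,ssf,mean,sd,entropy,kurtosis,skewness,mpp")
})

test_that("survival tables validate their clinical invariants", {
  good <- data.frame(
    patient_id = c("a", "b"), os_days = c(100, 200), os_event = c(1, 0),
    pfs_days = c(50, 210), pfs_event = c(1, 0), progressor = c(1, 0)
  )
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_survival_table(as_survival_table(good), tmp)
  back <- read_survival_table(tmp)
  expect_equal(as.data.frame(back), good, ignore_attr = TRUE)

  bad <- good; bad$pfs_days[1] <- 150; bad$os_days[1] <- 100
  expect_error(as_survival_table(bad), "pfs_days exceeds os_days")
  bad2 <- good; bad2$os_event[2] <- 2
  expect_error(as_survival_table(bad2), "binary")
  bad3 <- good; bad3$os_days[1] <- -1
  expect_error(as_survival_table(bad3), "non-negative")
})
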