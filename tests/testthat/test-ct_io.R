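test_that("NIfTI volume save/load round trip is value-exact", {
  vox <- array(-1000, c(20, 20, 5))
  vox[5, 7, 2] <- 350
  vol <- ct_volume(vox, c(0.7, 0.7, 2.5))
  path <- tempfile(fileext = ".nii.gz")
  save_ct(vol, path)
  back <- load_ct(path)
  expect_identical(dim(back$voxels), dim(vol$voxels))
  expect_equal(back$voxels, vol$voxels, ignore_attr = TRUE)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
})

test_that("mask round trip is bit-exact and carries voxel volume", {
  set.seed(0)
  bits <- array(runif(16 * 16 * 4) > 0.5, c(16, 16, 4))
  m <- binary_mask(bits, c(0.7, 0.7, 2.5))
  back <- mask_roundtrip(m, tempfile(fileext = ".nii.gz"))
  expect_identical(back$bits, m$bits)
  expect_equal(back$voxel_volume, 0.7 * 0.7 * 2.5, tolerance = 1e-6)

  empty <- binary_mask(array(FALSE, c(16, 16, 4)), c(0.7, 0.7, 2.5))
  back2 <- mask_roundtrip(empty, tempfile(fileext = ".nii.gz"))
  expect_identical(back2$voxel_count, 0L)
})

test_that("mask congruence against a declared parent grid is enforced", {
  m <- binary_mask(array(FALSE, c(8, 8, 2)), c(1, 1, 1))
  vol <- ct_volume(array(0, c(9, 8, 2)), c(1, 1, 1))
  expect_error(save_mask(m, tempfile(fileext = ".nii"), parent = vol),
               "does not match")
})

test_that("volume constructor validates spacing and clamps HU", {
  expect_error(ct_volume(array(0, c(4, 4, 2)), c(1, 0, 1)), "positive")
  v <- ct_volume(array(c(-3000, 9000, rep(0, 30)), c(4, 4, 2)), c(1, 1, 1))
  expect_equal(range(v$voxels), c(-1024, 4000))
})

test_that("grid standardization preserves physical extent and content", {
  # identity when already at target
  vol <- ct_volume(array(rnorm(64 * 64 * 3), c(64, 64, 3)), c(1.4, 1.4, 2.5))
  expect_identical(standardize_grid(vol, 64L), vol)

  up <- standardize_grid(vol, 128L)
  expect_equal(dim(up$voxels)[1:2], c(128L, 128L))
  expect_equal(up$spacing[1:2], c(0.7, 0.7), tolerance = 1e-9)
  expect_equal(128 * up$spacing[1], 64 * 1.4, tolerance = 1e-9)

  # a 100 mm^2 square insert keeps its area within 5% after resampling
  vox <- array(0, c(64, 64, 1))
  vox[20:29, 20:29, 1] <- 400  # 10x10 px at 1 mm = 100 mm^2
  sq <- ct_volume(vox, c(1, 1, 2.5), clamp = FALSE)
  rs <- standardize_grid(sq, 128L)
  area <- sum(rs$voxels >= 200) * prod(rs$spacing[1:2])
  expect_lt(abs(area - 100) / 100, 0.05)

  expect_error(standardize_grid(vol, 0L), "positive")
  tiny <- ct_volume(array(0, c(16, 16, 2)), c(1, 1, 1))
  expect_error(standardize_grid(tiny, 64L), ">= 32")
})

test_that("DICOM series load applies rescale and sorts superior first", {
  stored <- list(matrix(0L, 16, 16), matrix(100L, 16, 16),
                 matrix(1500L, 16, 16))
  stored[[1]][3, 5] <- 1200L  # row 3, column 5 of the top slice
  dir <- write_dicom_series(file.path(tempdir(), "dcm_ok"), stored,
                            pixel_spacing = c(0.6, 0.8), dz = 2.5,
                            slope = 1, intercept = -1024)
  vol <- load_ct(dir)
  expect_s3_class(vol, "ct_volume")
  expect_equal(dim(vol$voxels), c(16L, 16L, 3L))
  # stored 0 with slope 1 / intercept -1024 -> -1024 HU
  expect_equal(vol$voxels[1, 1, 1], -1024)
  expect_equal(vol$voxels[1, 1, 2], 100 - 1024)
  expect_equal(vol$voxels[1, 1, 3], 1500 - 1024)
  # in-plane layout: array[x, y] = stored[row = y, col = x]
  expect_equal(vol$voxels[5, 3, 1], 1200 - 1024)
  # PixelSpacing is (row, col); array axis 1 walks columns
  expect_equal(vol$spacing, c(0.8, 0.6, 2.5), tolerance = 1e-9)
})

test_that("mixed-series DICOM directories are rejected", {
  dir <- file.path(tempdir(), "dcm_mixed")
  dir.create(dir, showWarnings = FALSE)
  write_dicom_slice(file.path(dir, "a.dcm"), matrix(0L, 8, 8),
                    series_uid = "1.2.3", ipp = c(0, 0, 0))
  write_dicom_slice(file.path(dir, "b.dcm"), matrix(0L, 8, 8),
                    series_uid = "9.9.9", ipp = c(0, 0, 2.5))
  expect_error(load_ct(dir), "SeriesInstanceUID")
})

test_that("inconsistent slice positions raise a spacing error", {
  dir <- file.path(tempdir(), "dcm_gap")
  dir.create(dir, showWarnings = FALSE)
  for (i in 1:3)
    write_dicom_slice(file.path(dir, sprintf("s%d.dcm", i)),
                      matrix(0L, 8, 8), instance = i,
                      ipp = c(0, 0, c(0, 2.5, 7.5)[i]))
  expect_error(load_ct(dir), "slice spacing")
})

test_that("generated DICOM agrees with an independent reader (pydicom)", {
  stored <- list(matrix(sample(0:2000, 64), 8, 8))
  dir <- write_dicom_series(file.path(tempdir(), "dcm_x"), stored,
                            pixel_spacing = c(1.1, 0.9), dz = 3,
                            slope = 2, intercept = -1000)
  vol <- load_ct(dir)
  f <- list.files(dir, full.names = TRUE)[1]
  code <- paste0(
    "import pydicom, json, sys\n",
    "from pydicom.uid import ExplicitVRLittleEndian\n",
    "ds = pydicom.dcmread(sys.argv[1], force=True)\n",
    "ds.file_meta = pydicom.dataset.FileMetaDataset()\n",
    "ds.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian\n",
    "a = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)\n",
    "print(json.dumps({'sum': float(a.sum()), 'max': float(a.max()),\n",
    "  'v23': float(a[1, 2]), 'ps': [float(x) for x in ds.PixelSpacing]}))\n")
  out <- system2("python", c("-c", shQuote(code), shQuote(f)),
                 stdout = TRUE)
  ref <- jsonlite::fromJSON(out)
  expect_equal(sum(vol$voxels), ref$sum)
  expect_equal(max(vol$voxels), ref$max)
  # pydicom indexes [row, col] zero-based; our array is [col, row]
  expect_equal(vol$voxels[3, 2, 1], ref$v23)
})
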