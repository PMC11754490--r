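raster_disk <- function(n, r, cx = n / 2, cy = n / 2) {
  outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+") <= r^2
}

test_that("aorta cross-section shapes classify as expected", {
  disk <- raster_disk(40, 10)
  expect_equal(classify_aorta_shape(disk)$class, "circular")

  ell <- outer(((seq_len(60) - 30) / 20)^2, ((seq_len(60) - 30) / 10)^2,
               "+") <= 1
  cl <- classify_aorta_shape(ell)
  expect_equal(cl$class, "elliptical")
  expect_gt(cl$axis_ratio, 1.8)

  crescent <- ell & !raster_disk(60, 9, cx = 19, cy = 30)
  expect_equal(classify_aorta_shape(crescent)$class, "semi_elliptical")

  expect_equal(classify_aorta_shape(matrix(FALSE, 10, 10))$class, "absent")
})

test_that("phantom aorta profile recovers the spec's shape schedule", {
  ph <- shared_phantom()
  prof <- aorta_shape_profile(ph$truth$aorta)
  sched <- ph$truth$spec$geom$aorta
  expect_true(all(prof$class[sched$circular] == "circular"))
  expect_true(all(prof$class[sched$elliptical] == "elliptical"))
  expect_true(all(prof$class[sched$semi_elliptical] == "semi_elliptical"))
  expect_true(all(prof$class[-c(sched$circular, sched$elliptical,
                                sched$semi_elliptical)] == "absent"))
})

test_that("reference slice is the first elliptical slice, plus offset", {
  ph <- shared_phantom()
  prof <- aorta_shape_profile(ph$truth$aorta)
  ref <- find_reference_slice(prof, slice_spacing_mm = 2.5, offset_mm = 10)
  expect_equal(ref$reference, ph$truth$first_elliptical_slice)
  expect_equal(ref$localization, ref$reference + ceiling(10 / 2.5))
  expect_false(ref$fallback_used)

  # all-circular profile: error with fallback hint, or flagged fallback
  circ <- prof
  circ$class[circ$class == "elliptical"] <- "circular"
  expect_error(find_reference_slice(circ, 2.5), "allow_fallback")
  fb <- find_reference_slice(circ, 2.5, allow_fallback = TRUE)
  expect_true(fb$fallback_used)
  expect_equal(fb$reference, circ$slice[which.max(circ$n_pixels)])

  empty <- data.frame(slice = 1:3, class = "absent", axis_ratio = NA,
                      solidity = NA, n_pixels = 0L)
  expect_error(find_reference_slice(empty, 2.5), "empty")
})

test_that("the coronary corridor contains the fat mask and the lesions", {
  ph <- shared_phantom()
  corridor <- coronary_corridor(ph$truth$fat, 5, 5)
  expect_true(all(corridor$bits[ph$truth$fat$bits]))  # closing extensive
  for (l in ph$truth$lesions)
    expect_true(all(corridor$bits[l$idx]))

  empty <- binary_mask(array(FALSE, c(8, 8, 2)), c(1, 1, 1))
  expect_equal(coronary_corridor(empty)$voxel_count, 0L)
})

split_shared <- function(shift = NULL) {
  ph <- shared_phantom()
  t <- ph$truth
  heart <- t$heart; aorta <- t$aorta
  fat <- t$fat
  if (!is.null(shift)) {
    heart <- binary_mask(shift_array(heart$bits, shift, 1, FALSE),
                         heart$spacing)
    aorta <- binary_mask(shift_array(aorta$bits, shift, 1, FALSE),
                         aorta$spacing)
    fat <- binary_mask(shift_array(fat$bits, shift, 1, FALSE), fat$spacing)
  }
  corridor <- coronary_corridor(fat, 5, 5)
  prof <- aorta_shape_profile(aorta)
  ref <- find_reference_slice(prof, 2.5)
  split_heart_regions(heart, aorta, corridor, ref)
}

test_that("region map is an exclusive partition oriented by the aorta", {
  ph <- shared_phantom()
  rm <- split_shared()
  expect_s3_class(rm, "artery_region_map")
  # aorta voxels carry the AORTA label and never a coronary label
  expect_true(all(rm$labels[ph$truth$aorta$bits] == 1L))
  expect_false(any(rm$labels[!ph$truth$aorta$bits] == 1L))
  # coronary labels only at/below the localization slice
  above <- rm$labels[, , seq_len(rm$localization_slice - 1L)]
  expect_true(all(above %in% c(0L, 1L)))
  # every lesion voxel is labelled with its own artery >= 95%
  for (l in ph$truth$lesions) {
    want <- match(l$artery, c("AORTA", "RCA", "LAD", "LCX"))
    expect_gte(mean(rm$labels[l$idx] == want), 0.95)
  }
})

test_that("region labels are equivariant under in-plane translation", {
  rm0 <- split_shared()
  rm5 <- split_shared(shift = 5L)
  expect_identical(shift_array(rm0$labels, 5L, 1, 0L), rm5$labels)
})

test_that("degenerate inputs are rejected", {
  ph <- shared_phantom()
  t <- ph$truth
  ref <- list(reference = 6L, localization = 10L, fallback_used = FALSE)
  empty <- binary_mask(array(FALSE, dim(t$heart$bits)), t$heart$spacing)
  expect_error(split_heart_regions(empty, t$aorta, t$fat, ref),
               "heart mask is empty")
  expect_error(split_heart_regions(t$heart, empty, t$fat, ref),
               "aorta mask is empty")
})
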