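mk_vol <- function(vox, spacing = c(1, 1, 1))
  ct_volume(vox, spacing, clamp = FALSE)

test_that("candidate threshold is inclusive at 130 HU", {
  vox <- array(100, c(6, 6, 2))
  expect_equal(candidate_mask(mk_vol(vox))$voxel_count, 0L)

  vox[3, 3, 1] <- 130
  expect_equal(candidate_mask(mk_vol(vox))$voxel_count, 1L)

  toy <- array(c(120, 129, 130, 131, 200, 400, 90, 50, 135), c(3, 3, 1))
  expect_equal(candidate_mask(mk_vol(toy))$voxel_count, 5L)
})

test_that("noise suppression removes specks but keeps 2x2 components", {
  d <- c(16, 16, 3)
  vox <- array(0, d)
  vox[8, 8, 2] <- 135                 # isolated single voxel
  vox[2:4, 2:4, 1:2] <- 300           # solid 3x3x2 block
  vox[12:13, 12:13, 3] <- 200         # minimal 2x2 in-plane component
  vol <- mk_vol(vox)
  cand <- candidate_mask(vol)
  out <- suppress_noise(cand, vol)
  expect_false(out$bits[8, 8, 2])
  expect_true(all(out$bits[2:4, 2:4, 1:2]))
  expect_true(all(out$bits[12:13, 12:13, 3]))

  empty <- candidate_mask(mk_vol(array(0, d)))
  expect_equal(suppress_noise(empty, mk_vol(array(0, d)))$voxel_count, 0L)
})

test_that("the volume/peak noise filter is a joint (AND) condition", {
  d <- c(12, 12, 4)
  vox <- array(0, d)
  vox[2:3, 2:3, 1] <- 150    # small (4 voxels) AND faint -> removed
  vox[6:7, 6:7, 1] <- 500    # small but bright -> kept
  vol <- mk_vol(vox)
  p <- calcium_params(noise_min_voxels = 10L, noise_min_peak_hu = 160)
  out <- suppress_noise(candidate_mask(vol), vol, p)
  expect_false(any(out$bits[2:3, 2:3, 1]))
  expect_true(all(out$bits[6:7, 6:7, 1]))
})

test_that("bone removal merges and removes large groups with satellites", {
  d <- c(40, 40, 20)
  vox <- array(0, d)
  vox[5:28, 5:28, 1:18] <- 1000          # 10368 voxels > 10000: bone
  vox[31:32, 6:8, 5] <- 700              # fleck within 3 voxels of bone
  vox[36:38, 33:35, 15:18] <- 300        # distant small lesion, kept
  vol <- mk_vol(vox)
  mask <- candidate_mask(vol)
  out <- remove_bone(mask, vol)
  expect_false(any(out$bits[5:28, 5:28, 1:18]))
  expect_false(any(out$bits[31:32, 6:8, 5]))
  expect_true(all(out$bits[36:38, 33:35, 15:18]))

  # nothing above the merge threshold -> untouched
  small <- mk_vol(array(ifelse(array(seq_len(prod(d)), d) %% 97 == 0,
                               200, 0), d))
  sm <- candidate_mask(small)
  expect_identical(remove_bone(sm, small)$bits, sm$bits)
})

test_that("component recovery restores partially filtered lesions only", {
  d <- c(12, 12, 3)
  cand_bits <- array(FALSE, d)
  cand_bits[2:6, 2:6, 1:2] <- TRUE      # lesion component
  cand_bits[9:10, 9:10, 3] <- TRUE      # rejected noise component
  cand <- binary_mask(cand_bits, c(1, 1, 1))

  filt_bits <- array(FALSE, d)
  filt_bits[4, 4, 1] <- TRUE            # surviving core of the lesion
  filt <- binary_mask(filt_bits, c(1, 1, 1))

  out <- recover_components(filt, cand)
  expect_true(all(out$bits[2:6, 2:6, 1:2]))   # full component restored
  expect_false(any(out$bits[9:10, 9:10, 3]))  # disjoint stays excluded

  expect_identical(recover_components(cand, cand)$bits, cand$bits)
  bad_bits <- array(FALSE, d); bad_bits[12, 12, 3] <- TRUE
  expect_error(recover_components(binary_mask(bad_bits, c(1, 1, 1)), cand),
               "not a subset")
})

test_that("lesion attribution follows the cardiac mask and majority rule", {
  d <- c(20, 20, 4)
  vox <- array(0, d)
  vox[3:5, 3:5, 2] <- 250        # inside cardiac mask, straddles LAD/LCX
  vox[15:17, 15:17, 2] <- 400    # outside cardiac mask -> dropped
  vol <- mk_vol(vox)
  cardiac_bits <- array(FALSE, d); cardiac_bits[1:10, 1:10, ] <- TRUE
  cardiac <- binary_mask(cardiac_bits, c(1, 1, 1))

  labels <- array(0L, d)
  labels[3:5, 3:4, 2] <- 3L      # 6 voxels LAD
  labels[3:5, 5, 2] <- 4L        # 3 voxels LCX
  rm <- structure(list(labels = labels, spacing = c(1, 1, 1),
                       reference_slice = 1L, localization_slice = 1L,
                       fallback_used = FALSE),
                  class = "artery_region_map")
  lesions <- assign_lesions(candidate_mask(vol), cardiac, rm, vol)
  expect_length(lesions, 1L)
  expect_equal(lesions[[1]]$artery, "LAD")   # 6 vs 3 majority
  expect_equal(lesions[[1]]$n_voxels, 9L)
  sc <- lesions[[1]]$slice_components
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$area_mm2, 9)
  expect_equal(sc$max_hu, 250)
})

test_that("per-slice components are separated within one 3D lesion", {
  d <- c(20, 20, 2)
  vox <- array(0, d)
  vox[2:3, 2:3, 1] <- 150
  vox[2:3, 2:3, 2] <- 350        # same 3D lesion, brighter lower slice
  vox[6:7, 2:3, 2] <- 250        # second in-plane component, same slice,
  vox[4:5, 2:3, 1] <- 135        # bridge making it all one 3D component
  vol <- mk_vol(vox)
  all_mask <- binary_mask(array(TRUE, d), c(1, 1, 1))
  labels <- array(2L, d)         # everything RCA
  rm <- structure(list(labels = labels, spacing = c(1, 1, 1),
                       reference_slice = 1L, localization_slice = 1L,
                       fallback_used = FALSE),
                  class = "artery_region_map")
  lesions <- assign_lesions(candidate_mask(vol), all_mask, rm, vol)
  expect_length(lesions, 1L)
  sc <- lesions[[1]]$slice_components
  # slice 1: one 8-connected component (bridge), slice 2: two components
  expect_equal(sum(sc$slice == 1), 1L)
  expect_equal(sum(sc$slice == 2), 2L)
  expect_setequal(sc$max_hu[sc$slice == 2], c(350, 250))
})

test_that("every cascade stage output stays within the candidate mask", {
  ph <- shared_phantom()
  vol <- ph$volume
  p <- calcium_params()
  cand <- candidate_mask(vol, p$hu_min)
  s1 <- suppress_noise(cand, vol, p)
  s2 <- remove_bone(s1, vol, p)
  s3 <- recover_components(s2, cand, p)
  expect_true(all(cand$bits[s1$bits]))
  expect_true(all(s1$bits[s2$bits]))
  expect_true(all(cand$bits[s3$bits]))
})

test_that("cascade parameters are validated", {
  expect_error(calcium_params(hu_min = -1), "hu_min")
  expect_error(calcium_params(bone_merge_voxels = 2, noise_min_voxels = 3),
               "bone_merge_voxels")
  expect_error(calcium_params(connectivity = 10), "connectivity")
})
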