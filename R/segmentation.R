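#' Bundle heart / aorta / epicardial fat masks
#'
#' The output contract of any segmentation backend: three binary masks
#' congruent with the volume grid. The epicardial fat mask must lie on
#' the epicardial surface, i.e. within a small dilation of the heart.
#'
#' @param heart,aorta,epicardial_fat [binary_mask()] objects on one grid.
#' @return object of class `organ_mask_set`.
#' @export
organ_mask_set <- function(heart, aorta, epicardial_fat) {
  check_congruent(aorta, heart)
  check_congruent(epicardial_fat, heart)
  structure(list(heart = heart, aorta = aorta,
                 epicardial_fat = epicardial_fat),
            class = "organ_mask_set")
}

#' Reference organ segmentation for phantom-like volumes
#'
#' A deterministic density/geometry backend standing in the seat a
#' trained segmentation network occupies in production: it thresholds a
#' soft-tissue window, discards the chest-wall component (any component
#' touching the body-wall shell), takes the largest remaining component
#' as the heart (closed with a small ball), picks the largest remaining
#' multi-slice component as the aorta, and derives epicardial fat from
#' the heart mask. Valid on phantoms and phantom-like data; masks from
#' any external model can be injected instead via [file_backend()].
#'
#' @param vol a standardized [ct_volume()].
#' @param soft_window HU window for cardiac/mediastinal soft tissue.
#' @param body_hu_min HU floor defining the body (excludes air and lung).
#' @param close_mm closing radius applied to the heart mask, mm.
#' @param min_component_voxels ignore soft-tissue specks below this size.
#' @param fat_hu_range,fat_shell_mm passed to [derive_epicardial_fat()].
#' @return an [organ_mask_set()].
#' @export
segment_reference <- function(vol, soft_window = c(-300, 300),
                              body_hu_min = -500, close_mm = 3,
                              min_component_voxels = 200L,
                              fat_hu_range = c(-190, -30),
                              fat_shell_mm = 10) {
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume")
  d <- dim(vol$voxels)
  body_bits <- vol$voxels >= body_hu_min
  if (!any(body_bits)) stop("no heart candidate: volume contains no tissue")
  blab <- label_components(body_bits, 26L)
  bsizes <- tabulate(blab[blab > 0])
  body <- as_mask(blab == which.max(bsizes), vol)

  soft_bits <- vol$voxels >= soft_window[1] & vol$voxels <= soft_window[2]
  lab <- label_components(soft_bits, 26L)
  sizes <- tabulate(lab[lab > 0])
  wall_ids <- unique(lab[body$bits & lab > 0])
  cand <- setdiff(which(sizes >= min_component_voxels), wall_ids)
  if (length(cand) == 0L)
    stop("no heart candidate: no soft-tissue component inside the thorax")

  heart_id <- cand[which.max(sizes[cand])]
  heart <- mask_close_mm(as_mask(lab == heart_id, vol), close_mm)

  rest <- setdiff(cand, heart_id)
  aorta_bits <- array(FALSE, d)
  if (length(rest) > 0L) {
    # tube-like: spans several slices; take the largest such component
    spans <- vapply(rest, function(id) {
      z <- unique(arrayInd(which(lab == id), d)[, 3])
      length(z)
    }, integer(1))
    tubes <- rest[spans >= 3L]
    if (length(tubes) > 0L) {
      aorta_id <- tubes[which.max(sizes[tubes])]
      aorta_bits <- mask_close_mm(as_mask(lab == aorta_id, vol), 2)$bits
    }
  }
  aorta <- as_mask(aorta_bits, vol)
  fat <- derive_epicardial_fat(vol, heart, fat_hu_range, fat_shell_mm)
  organ_mask_set(heart, aorta, fat)
}

#' Derive the epicardial fat mask from the heart mask
#'
#' Epicardial fat occupies a fixed attenuation window and lies on the
#' epicardial surface, so it is recovered as the voxels inside
#' `fat_hu_range` within a shell around the heart boundary (heart
#' dilated by `shell_mm` minus heart eroded by `shell_mm`). Components
#' below `min_voxels` are discarded. An empty result is legal (a
#' fat-free volume).
#'
#' @param vol a [ct_volume()].
#' @param heart_mask nonempty heart [binary_mask()].
#' @param fat_hu_range HU window, default the adipose window
#'   `c(-190, -30)`.
#' @param shell_mm half-width of the boundary shell, mm.
#' @param min_voxels small-component floor.
#' @return a [binary_mask()].
#' @export
derive_epicardial_fat <- function(vol, heart_mask,
                                  fat_hu_range = c(-190, -30),
                                  shell_mm = 10, min_voxels = 10L) {
  check_congruent(heart_mask, vol)
  if (heart_mask$voxel_count == 0L) stop("`heart_mask` is empty")
  shell <- mask_dilate_mm(heart_mask, shell_mm)$bits &
    !mask_erode_mm(heart_mask, shell_mm)$bits
  bits <- shell & vol$voxels >= fat_hu_range[1] &
    vol$voxels <= fat_hu_range[2]
  if (any(bits) && min_voxels > 1L) {
    lab <- label_components(bits, 26L)
    sizes <- tabulate(lab[lab > 0])
    bits <- array(lab > 0 & sizes[pmax(lab, 1L)] >= min_voxels, dim(bits))
  }
  as_mask(bits, vol)
}

#' Segmentation backends
#'
#' A backend is a list with a `name` and a `segment(vol)` function
#' returning an [organ_mask_set()]. `reference_backend()` wraps
#' [segment_reference()]; `file_backend()` injects masks produced by any
#' external model (e.g. a trained network) from NIfTI files, deriving
#' the fat mask from the heart mask when no fat file is given.
#'
#' @param ... parameters forwarded to [segment_reference()].
#' @return a backend list.
#' @export
reference_backend <- function(...) {
  args <- list(...)
  list(name = "reference",
       segment = function(vol) do.call(segment_reference, c(list(vol), args)))
}

#' @rdname reference_backend
#' @param heart_path,aorta_path NIfTI mask files (required).
#' @param fat_path optional NIfTI fat mask file.
#' @export
file_backend <- function(heart_path, aorta_path, fat_path = NULL) {
  force(heart_path); force(aorta_path); force(fat_path)
  list(name = "files",
       segment = function(vol) {
         heart <- load_mask(heart_path)
         aorta <- load_mask(aorta_path)
         fat <- if (is.null(fat_path))
           derive_epicardial_fat(vol, heart) else load_mask(fat_path)
         organ_mask_set(heart, aorta, fat)
       })
}
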