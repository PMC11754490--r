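# The calcium-candidate cascade: threshold at 130 HU, per-slice
# morphological opening against speckle noise, a joint volume/peak
# filter, bone elimination by 3D dilation of very large components,
# connected-component recovery of partially eroded lesions, cardiac
# masking, and per-artery lesion attribution.

#' Calcium cascade parameters
#'
#' @param hu_min candidate threshold in HU (>= 130 is the Agatston
#'   convention; the threshold is inclusive).
#' @param noise_min_voxels components smaller than this AND fainter than
#'   `noise_min_peak_hu` are discarded as noise.
#' @param noise_min_peak_hu peak-HU floor of the joint noise filter.
#' @param bone_merge_voxels components larger than this are treated as
#'   bone seeds (default 10000 voxels).
#' @param bone_dilate_radius 3D dilation radius (voxels) used to merge
#'   small bone fragments into their parent bone component.
#' @param connectivity 3D component connectivity (6, 18 or 26).
#' @param connectivity_2d in-plane component connectivity (4 or 8).
#' @return list of validated parameters.
#' @export
calcium_params <- function(hu_min = 130, noise_min_voxels = 3L,
                           noise_min_peak_hu = 160,
                           bone_merge_voxels = 10000L,
                           bone_dilate_radius = 3L,
                           connectivity = 26L, connectivity_2d = 8L) {
  if (hu_min < 0) stop("`hu_min` must be >= 0")
  if (bone_merge_voxels <= noise_min_voxels)
    stop("`bone_merge_voxels` must exceed `noise_min_voxels`")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  if (!connectivity_2d %in% c(4L, 8L))
    stop("`connectivity_2d` must be 4 or 8")
  list(hu_min = hu_min, noise_min_voxels = as.integer(noise_min_voxels),
       noise_min_peak_hu = noise_min_peak_hu,
       bone_merge_voxels = as.integer(bone_merge_voxels),
       bone_dilate_radius = as.integer(bone_dilate_radius),
       connectivity = as.integer(connectivity),
       connectivity_2d = as.integer(connectivity_2d))
}

#' Threshold a volume into a calcium candidate mask
#'
#' @param vol a [ct_volume()].
#' @param hu_min inclusive threshold (default 130 HU).
#' @return a [binary_mask()] of voxels with HU >= `hu_min`.
#' @export
candidate_mask <- function(vol, hu_min = 130) {
  as_mask(vol$voxels >= hu_min, vol)
}

# per-component peak HU for a labelled mask
component_peaks <- function(lab, vol, ids) {
  set <- lab > 0
  vals <- vol$voxels[set]
  labs <- lab[set]
  peaks <- vapply(split(vals, labs), max, numeric(1))
  peaks[as.character(ids)]
}

#' Suppress speckle noise in a candidate mask
#'
#' Two stages: (1) a per-slice morphological opening with a 2x2 square
#' structuring element, which deletes isolated pixels and thin specks
#' while keeping any component at least 2x2 in-plane; (2) removal of 3D
#' components that are BOTH smaller than `noise_min_voxels` AND fainter
#' than `noise_min_peak_hu` (the joint condition keeps tiny-but-bright
#' and large-but-faint components).
#'
#' @param mask candidate [binary_mask()].
#' @param vol the HU [ct_volume()] the mask was thresholded from.
#' @param params [calcium_params()].
#' @return a [binary_mask()] (subset of `mask`).
#' @export
suppress_noise <- function(mask, vol, params = calcium_params()) {
  check_congruent(mask, vol)
  d <- dim(mask$bits)
  se <- cbind(dx = c(0L, 1L, 0L, 1L), dy = c(0L, 0L, 1L, 1L),
              dz = c(0L, 0L, 0L, 0L))
  er <- cpp_morph_offsets(mask$bits, d, se, FALSE)
  op <- cpp_morph_offsets(er, d, se, TRUE)
  bits <- array(op, d) & mask$bits

  if (any(bits)) {
    lab <- label_components(bits, params$connectivity)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < params$noise_min_voxels)
    if (length(small) > 0L) {
      peaks <- component_peaks(lab, vol, small)
      drop <- small[peaks < params$noise_min_peak_hu]
      if (length(drop) > 0L) bits[lab %in% drop] <- FALSE
    }
  }
  as_mask(bits, mask)
}

#' Eliminate bone from a calcium mask
#'
#' Components with more than `bone_merge_voxels` voxels are taken as
#' bone, dilated in 3D so nearby small bone fragments merge with them,
#' and every component intersecting a dilated bone seed is removed
#' together with it. Coronary lesions far from bone are untouched.
#'
#' @param mask noise-suppressed [binary_mask()].
#' @param vol the HU [ct_volume()] (unused by the default rule; part of
#'   the stage contract so density-aware variants can slot in).
#' @param params [calcium_params()].
#' @return a [binary_mask()] (subset of `mask`).
#' @export
remove_bone <- function(mask, vol, params = calcium_params()) {
  bits <- mask$bits
  if (!any(bits)) return(mask)
  lab <- label_components(bits, params$connectivity)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes > params$bone_merge_voxels)
  if (length(big) == 0L) return(mask)
  seed <- as_mask(array(lab %in% big, dim(bits)), mask)
  grown <- morph(seed, params$bone_dilate_radius, params$connectivity,
                 "dilate")
  hit <- unique(lab[grown$bits & lab > 0])
  bits[lab %in% hit] <- FALSE
  as_mask(bits, mask)
}

#' Recover candidate components partially removed by filtering
#'
#' Any candidate 3D component that still intersects the filtered mask is
#' restored in full; components wiped out entirely stay excluded. This
#' undoes partial erosion of true lesions by the noise/bone stages
#' without readmitting components that were rejected outright.
#'
#' @param filtered [binary_mask()], must be a subset of `candidates`.
#' @param candidates the original candidate [binary_mask()].
#' @param params [calcium_params()].
#' @return a [binary_mask()] with `filtered` <= result <= `candidates`.
#' @export
recover_components <- function(filtered, candidates,
                               params = calcium_params()) {
  check_congruent(filtered, candidates)
  if (any(filtered$bits & !candidates$bits))
    stop("`filtered` is not a subset of `candidates`")
  if (!any(filtered$bits)) return(filtered)
  lab <- label_components(candidates$bits, params$connectivity)
  keep <- unique(lab[filtered$bits])
  keep <- keep[keep > 0]
  as_mask(array(lab %in% keep, dim(lab)), candidates)
}

#' Attribute calcium components to arteries
#'
#' Applies the cardiac mask (voxel-wise), re-labels the surviving
#' calcium into 3D components, and assigns each component the region
#' label held by the majority of its voxels (ties broken by overlap
#' count, then by the fixed order AORTA < RCA < LAD < LCX so reruns are
#' deterministic). Components with no labelled voxel at all cannot be
#' attributed and are dropped. For each lesion the per-slice 2D
#' connected components are computed with their areas (mm^2) and maxima
#' (HU) - the inputs of Agatston scoring.
#'
#' @param mask final calcium [binary_mask()].
#' @param cardiac_mask heart-plus-aorta [binary_mask()]; calcium outside
#'   it is extra-cardiac and discarded.
#' @param region_map an `artery_region_map` from
#'   [split_heart_regions()].
#' @param vol the HU [ct_volume()].
#' @param params [calcium_params()].
#' @return list of `calcium_lesion` objects: `artery`, `idx` (linear
#'   voxel indices), `n_voxels`, `volume_mm3`, `peak_hu`,
#'   `slice_components` (data.frame slice/area_mm2/max_hu/n_pixels).
#' @export
assign_lesions <- function(mask, cardiac_mask, region_map, vol,
                           params = calcium_params()) {
  check_congruent(mask, vol)
  check_congruent(cardiac_mask, vol)
  d <- dim(vol$voxels)
  pix <- vol$spacing[1] * vol$spacing[2]
  bits <- mask$bits & cardiac_mask$bits
  if (!any(bits)) return(list())
  lab <- label_components(bits, params$connectivity)
  n_comp <- max(lab)
  lesions <- list()
  for (k in seq_len(n_comp)) {
    idx <- which(lab == k)
    rl <- region_map$labels[idx]
    rl <- rl[rl > 0]
    if (length(rl) == 0L) next  # unattributable component
    counts <- tabulate(rl, nbins = 4L)
    artery <- REGION_LEVELS[which.max(counts)]  # ties: fixed label order
    ijk <- arrayInd(idx, d)
    hu <- vol$voxels[idx]
    comps <- lapply(sort(unique(ijk[, 3])), function(z) {
      sel <- ijk[, 3] == z
      sl <- array(FALSE, c(d[1], d[2], 1L))
      sl[cbind(ijk[sel, 1:2, drop = FALSE], 1L)] <- TRUE
      lab2 <- label_components(sl, params$connectivity_2d)
      l2 <- lab2[cbind(ijk[sel, 1:2, drop = FALSE], 1L)]
      hz <- hu[sel]
      m <- max(l2)
      cnt <- tabulate(l2, nbins = m)
      mx <- vapply(split(hz, factor(l2, levels = seq_len(m))), max,
                   numeric(1))
      data.frame(slice = z, area_mm2 = cnt * pix,
                 max_hu = as.numeric(mx), n_pixels = cnt)
    })
    sc <- do.call(rbind, comps)
    lesions[[length(lesions) + 1L]] <- structure(
      list(artery = artery, idx = idx, n_voxels = length(idx),
           volume_mm3 = length(idx) * prod(vol$spacing),
           peak_hu = max(hu), slice_components = sc),
      class = "calcium_lesion")
  }
  lesions
}

#' Tabulate lesions for export
#'
#' @param lesions list of `calcium_lesion` objects.
#' @return data.frame with one row per lesion: artery, voxels, volume
#'   (mm^3), peak HU and Agatston contribution.
#' @export
lesion_table <- function(lesions) {
  if (length(lesions) == 0L)
    return(data.frame(artery = character(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), peak_hu = numeric(0),
                      score = numeric(0)))
  do.call(rbind, lapply(lesions, function(l) {
    data.frame(artery = l$artery, n_voxels = l$n_voxels,
               volume_mm3 = l$volume_mm3, peak_hu = l$peak_hu,
               score = sum(slice_component_score(l$slice_components$area_mm2,
                                                 l$slice_components$max_hu)))
  }))
}
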