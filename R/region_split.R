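# Heart region splitting: the aorta's axial cross-section progresses
# circular -> elliptical -> semi-elliptical -> absent when iterating from
# the most superior slice. The first elliptical slice anchors a
# localization slice a few mm below it; from there down the heart is
# split into RCA / LAD / LCX angular sectors around the per-slice heart
# centroid, oriented by the aorta centroid, while the aorta mask itself
# is labelled AORTA throughout.

#' Classify the shape of one axial aorta cross-section
#'
#' Fits second moments to the set pixels: `circular` when the principal
#' axis ratio is below `ratio_threshold`; `elliptical` when the ratio is
#' at or above it and the shape is solid (solidity >=
#' `solidity_threshold`); `semi_elliptical` when solidity falls below
#' the threshold (a notched/concave cross-section); `absent` when empty.
#'
#' @param slice_mask 2D logical matrix.
#' @param spacing in-plane spacing `(sx, sy)` in mm.
#' @param ratio_threshold axis-ratio boundary circular/elliptical.
#' @param solidity_threshold solidity boundary elliptical/semi.
#' @return list with `class`, `axis_ratio`, `solidity`, `n_pixels`.
#' @export
classify_aorta_shape <- function(slice_mask, spacing = c(1, 1),
                                 ratio_threshold = 1.25,
                                 solidity_threshold = 0.9) {
  n <- sum(slice_mask)
  if (n == 0L)
    return(list(class = "absent", axis_ratio = NA_real_,
                solidity = NA_real_, n_pixels = 0L))
  ij <- which(slice_mask, arr.ind = TRUE)
  pts <- cbind(ij[, 1] * spacing[1], ij[, 2] * spacing[2])
  if (n < 8L)
    return(list(class = "circular", axis_ratio = 1, solidity = 1,
                n_pixels = n))
  ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
  ratio <- sqrt(max(ev) / max(min(ev), 1e-12))
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  hull_area <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                       hp[, 2] * c(hp[-1, 1], hp[1, 1]))) / 2
  solidity <- min(1, n * spacing[1] * spacing[2] / max(hull_area, 1e-12))
  cls <- if (solidity < solidity_threshold) "semi_elliptical"
         else if (ratio >= ratio_threshold) "elliptical"
         else "circular"
  list(class = cls, axis_ratio = ratio, solidity = solidity, n_pixels = n)
}

#' Axial shape profile of an aorta mask
#'
#' @param aorta_mask aorta [binary_mask()].
#' @param ... thresholds passed to [classify_aorta_shape()].
#' @return data.frame with one row per slice: `slice`, `class`,
#'   `axis_ratio`, `solidity`, `n_pixels`.
#' @export
aorta_shape_profile <- function(aorta_mask, ...) {
  d <- dim(aorta_mask$bits)
  rows <- lapply(seq_len(d[3]), function(z) {
    cl <- classify_aorta_shape(aorta_mask$bits[, , z],
                               aorta_mask$spacing[1:2], ...)
    data.frame(slice = z, class = cl$class, axis_ratio = cl$axis_ratio,
               solidity = cl$solidity, n_pixels = cl$n_pixels)
  })
  do.call(rbind, rows)
}

#' Reference and localization slice from an aorta shape profile
#'
#' Iterating from the top, the first slice classified elliptical is the
#' reference; the localization slice for heart splitting lies
#' `offset_mm` below it. When no slice is elliptical, the default is an
#' error advising the fallback; with `allow_fallback = TRUE` the slice
#' of maximum aorta area is used instead and flagged, so scoring never
#' aborts on shape-classifier noise.
#'
#' @param profile data.frame from [aorta_shape_profile()].
#' @param slice_spacing_mm slice spacing (mm).
#' @param offset_mm craniocaudal offset to the localization slice.
#' @param allow_fallback use the maximum-area slice when no elliptical
#'   slice exists.
#' @return list with `reference`, `localization`, `fallback_used`.
#' @export
find_reference_slice <- function(profile, slice_spacing_mm,
                                 offset_mm = 10, allow_fallback = FALSE) {
  if (nrow(profile) == 0L || all(profile$class == "absent"))
    stop("aorta profile is empty: no aorta mask on any slice")
  ell <- profile$slice[profile$class == "elliptical"]
  fallback <- FALSE
  if (length(ell) > 0L) {
    ref <- min(ell)
  } else if (allow_fallback) {
    ref <- profile$slice[which.max(profile$n_pixels)]
    fallback <- TRUE
  } else {
    stop("no elliptical aorta slice found; set allow_fallback = TRUE ",
         "to use the maximum-area slice instead")
  }
  list(reference = ref,
       localization = ref + ceiling(offset_mm / slice_spacing_mm),
       fallback_used = fallback)
}

#' Coronary corridor from the epicardial fat mask
#'
#' The coronary arteries run in grooves within the epicardial fat, so a
#' morphological closing (dilate then erode, Euclidean ball in mm) of
#' the fat mask fills those grooves; the result is a superset of the fat
#' mask that contains the coronary calcium.
#'
#' @param fat_mask epicardial fat [binary_mask()].
#' @param dilate_mm,erode_mm closing radii in mm.
#' @return a [binary_mask()].
#' @export
coronary_corridor <- function(fat_mask, dilate_mm = 5, erode_mm = 5) {
  mask_close_mm(fat_mask, dilate_mm, erode_mm)
}

REGION_LEVELS <- c("AORTA", "RCA", "LAD", "LCX")

#' Split the heart into AORTA / RCA / LAD / LCX regions
#'
#' The aorta mask is labelled AORTA on every slice. On slices at or
#' below the localization slice, corridor voxels inside the heart (and
#' not aorta) are labelled by the angular sector of their position
#' around the per-slice heart centroid, measured counter-clockwise from
#' the heart-centroid-to-aorta axis: RCA in `sectors$rca`, LAD in
#' `sectors$lad`, LCX in the remainder. Slices above the localization
#' slice contribute the AORTA label only. Labels are mutually exclusive
#' by construction.
#'
#' @param heart,aorta,corridor [binary_mask()] objects on one grid.
#' @param reference list from [find_reference_slice()].
#' @param sectors list with numeric ranges (degrees) `rca` and `lad`;
#'   the sectors are read counter-clockwise starting at `rca[1]`.
#' @return object of class `artery_region_map`: integer label array
#'   (`0` background, `1` AORTA, `2` RCA, `3` LAD, `4` LCX) plus
#'   `reference_slice`, `localization_slice`, `fallback_used`.
#' @export
split_heart_regions <- function(heart, aorta, corridor, reference,
                                sectors = list(rca = c(-100, 80),
                                               lad = c(80, 200))) {
  check_congruent(aorta, heart)
  check_congruent(corridor, heart)
  if (heart$voxel_count == 0L) stop("heart mask is empty")
  if (aorta$voxel_count == 0L)
    stop("aorta mask is empty: cannot orient coronary sectors")
  d <- dim(heart$bits)
  sx <- heart$spacing[1]; sy <- heart$spacing[2]
  labels <- array(0L, d)
  labels[aorta$bits] <- 1L

  loc <- reference$localization
  cor_idx <- which(corridor$bits & heart$bits & !aorta$bits)
  if (length(cor_idx) > 0L) {
    ijk <- arrayInd(cor_idx, d)
    keep <- ijk[, 3] >= loc
    cor_idx <- cor_idx[keep]; ijk <- ijk[keep, , drop = FALSE]
  }
  if (length(cor_idx) > 0L) {
    hidx <- which(heart$bits)
    hijk <- arrayInd(hidx, d)
    cx <- tapply(hijk[, 1] * sx, hijk[, 3], mean)
    cy <- tapply(hijk[, 2] * sy, hijk[, 3], mean)
    aijk <- arrayInd(which(aorta$bits), d)
    a_xy <- c(mean(aijk[, 1]) * sx, mean(aijk[, 2]) * sy)

    zkey <- as.character(ijk[, 3])
    dxv <- a_xy[1] - cx[zkey]
    dyv <- a_xy[2] - cy[zkey]
    vx <- ijk[, 1] * sx - cx[zkey]
    vy <- ijk[, 2] * sy - cy[zkey]
    theta <- atan2(dxv * vy - dyv * vx, dxv * vx + dyv * vy) * 180 / pi
    phi <- (theta - sectors$rca[1]) %% 360
    w_rca <- (sectors$rca[2] - sectors$rca[1]) %% 360
    w_lad <- (sectors$lad[2] - sectors$rca[1]) %% 360
    lab <- ifelse(phi < w_rca, 2L, ifelse(phi < w_lad, 3L, 4L))
    labels[cor_idx] <- lab
  }
  structure(list(labels = labels, spacing = heart$spacing,
                 reference_slice = reference$reference,
                 localization_slice = loc,
                 fallback_used = isTRUE(reference$fallback_used)),
            class = "artery_region_map")
}

#' @export
print.artery_region_map <- function(x, ...) {
  counts <- tabulate(x$labels[x$labels > 0], nbins = 4L)
  cat("<artery_region_map>\n")
  cat(sprintf("  reference slice %d, localization slice %d%s\n",
              x$reference_slice, x$localization_slice,
              if (x$fallback_used) " (fallback: max-area slice)" else ""))
  for (k in 1:4)
    cat(sprintf("  %-6s %d voxels\n", REGION_LEVELS[k], counts[k]))
  invisible(x)
}
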