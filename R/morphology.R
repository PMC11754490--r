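#' Structuring-element offsets for a given connectivity
#'
#' Builds the voxel offsets of a "ball" of the requested radius under the
#' metric implied by the connectivity: 4 (2D diamond), 8 (2D square),
#' 6 (3D L1 ball), 18 (3D, Chebyshev radius r with L1 bound 2r) or
#' 26 (3D Chebyshev cube). 2D elements are flat (no out-of-slice term)
#' and are applied slice by slice.
#'
#' @param radius integer radius in voxels, >= 1.
#' @param connectivity one of 4, 8 (2D) or 6, 18, 26 (3D).
#' @return integer matrix with columns dx, dy, dz.
#' @export
se_offsets <- function(radius = 1L, connectivity = 26L) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("`radius` must be >= 1")
  connectivity <- as.integer(connectivity)
  r <- radius
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- switch(as.character(connectivity),
    "4"  = g$dz == 0 & abs(g$dx) + abs(g$dy) <= r,
    "8"  = g$dz == 0 & pmax(abs(g$dx), abs(g$dy)) <= r,
    "6"  = abs(g$dx) + abs(g$dy) + abs(g$dz) <= r,
    "18" = pmax(abs(g$dx), abs(g$dy), abs(g$dz)) <= r &
           abs(g$dx) + abs(g$dy) + abs(g$dz) <= 2L * r,
    "26" = pmax(abs(g$dx), abs(g$dy), abs(g$dz)) <= r,
    stop("unknown connectivity ", connectivity,
         " (expected 4, 8, 6, 18 or 26)"))
  as.matrix(g[keep, , drop = FALSE])
}

#' Binary dilation or erosion
#'
#' Morphological dilation (extensive: the input is a subset of the
#' output) or erosion (anti-extensive) of a binary mask with a ball
#' structuring element defined by `radius` and `connectivity`. Elements
#' with 2D connectivity (4/8) act within each axial slice independently.
#'
#' @param mask a [binary_mask()].
#' @param radius structuring element radius in voxels.
#' @param connectivity 4, 8, 6, 18 or 26 (see [se_offsets()]).
#' @param mode `"dilate"` or `"erode"`.
#' @return a [binary_mask()] on the same grid.
#' @export
morph <- function(mask, radius = 1L, connectivity = 26L,
                  mode = c("dilate", "erode")) {
  mode <- match.arg(mode)
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  off <- se_offsets(radius, connectivity)
  d <- dim(mask$bits)
  out <- cpp_morph_offsets(mask$bits, d, off, mode == "dilate")
  as_mask(array(out, d), mask)
}

# Euclidean-metric morphology in physical units via the exact distance
# transform; used for the mm-sized operations (fat shell, corridor
# closing) where the voxel grid is anisotropic. The transform runs on
# the mask's padded bounding box only; the pad layer is background, which
# matches the whole-array convention (outside the grid is background).
mask_bbox <- function(bits, pad) {
  idx <- which(bits)
  if (length(idx) == 0L) return(NULL)
  ijk <- arrayInd(idx, dim(bits))
  d <- dim(bits)
  lapply(1:3, function(a) {
    c(max(1L, min(ijk[, a]) - pad[a]), min(d[a], max(ijk[, a]) + pad[a]))
  })
}

mask_dilate_mm <- function(mask, radius_mm) {
  if (radius_mm <= 0) return(mask)
  d <- dim(mask$bits)
  pad <- ceiling(radius_mm / mask$spacing) + 1L
  bb <- mask_bbox(mask$bits, pad)
  if (is.null(bb)) return(mask)
  sub <- mask$bits[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
                   bb[[3]][1]:bb[[3]][2], drop = FALSE]
  dist2 <- cpp_edt_sq(sub, dim(sub), mask$spacing)
  out <- array(FALSE, d)
  out[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
      bb[[3]][1]:bb[[3]][2]] <- dist2 <= radius_mm^2
  as_mask(out, mask)
}

mask_erode_mm <- function(mask, radius_mm) {
  if (radius_mm <= 0) return(mask)
  d <- dim(mask$bits)
  bb <- mask_bbox(mask$bits, c(0L, 0L, 0L))
  if (is.null(bb)) return(mask)
  ds <- vapply(bb, function(r) r[2] - r[1] + 1L, integer(1))
  # one-voxel explicit background border so border voxels erode correctly
  sub <- array(FALSE, ds + 2L)
  sub[2:(ds[1] + 1L), 2:(ds[2] + 1L), 2:(ds[3] + 1L)] <-
    mask$bits[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
              bb[[3]][1]:bb[[3]][2], drop = FALSE]
  dist2 <- array(cpp_edt_sq(!sub, dim(sub), mask$spacing), dim(sub))
  keep <- dist2[2:(ds[1] + 1L), 2:(ds[2] + 1L), 2:(ds[3] + 1L)] >
    radius_mm^2
  out <- array(FALSE, d)
  out[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
      bb[[3]][1]:bb[[3]][2]] <-
    mask$bits[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
              bb[[3]][1]:bb[[3]][2], drop = FALSE] & keep
  as_mask(out, mask)
}

mask_close_mm <- function(mask, dilate_mm, erode_mm = dilate_mm) {
  mask_erode_mm(mask_dilate_mm(mask, dilate_mm), erode_mm)
}

#' Label connected components of a mask
#'
#' Deterministic flood-fill labelling (labels assigned in array scan
#' order). 2D connectivities label each axial slice independently.
#'
#' @param mask a [binary_mask()] or logical 3D array.
#' @param connectivity 4, 8 (2D, per slice) or 6, 18, 26 (3D).
#' @param spacing spacing, required only when `mask` is a bare array.
#' @return integer 3D array; 0 is background, components are 1..k.
#' @export
label_components <- function(mask, connectivity = 26L, spacing = NULL) {
  bits <- if (inherits(mask, "binary_mask")) mask$bits else mask
  d <- dim(bits)
  off <- se_offsets(1L, connectivity)
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE]
  if (!is.logical(bits)) storage.mode(bits) <- "logical"
  array(cpp_label_components(bits, d, off), d)
}
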