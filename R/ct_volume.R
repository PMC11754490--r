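#' CT volume container
#'
#' A calibrated 3D grid of attenuation values in Hounsfield units (HU)
#' with physical voxel spacing. Axial slices run along the third array
#' axis and slice 1 is the most superior slice.
#'
#' @param voxels numeric or integer 3D array of HU values.
#' @param spacing numeric length-3 vector `(sx, sy, sz)` in mm per axis;
#'   all entries must be strictly positive.
#' @param clamp if `TRUE` (default), values are clamped to the calibrated
#'   HU range \[-1024, 4000\].
#' @return An object of class `ct_volume` with fields `voxels` and
#'   `spacing`.
#' @export
ct_volume <- function(voxels, spacing, clamp = TRUE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (clamp) {
    voxels[voxels < -1024] <- -1024
    voxels[voxels > 4000] <- 4000
  }
  structure(list(voxels = voxels, spacing = spacing),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%g, %g]; slice 1 = most superior\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Binary mask on a CT grid
#'
#' A boolean grid congruent with a [ct_volume()] grid, carrying the grid
#' spacing so physical voxel volume is always available.
#'
#' @param bits logical 3D array.
#' @param spacing numeric length-3 spacing in mm (usually the parent
#'   volume's spacing).
#' @return An object of class `binary_mask` with fields `bits`,
#'   `spacing`, `voxel_count` and `voxel_volume` (mm^3 per voxel).
#' @export
binary_mask <- function(bits, spacing) {
  if (!is.array(bits) || length(dim(bits)) != 3L)
    stop("`bits` must be a 3D array")
  if (!is.logical(bits)) {
    storage.mode(bits) <- "logical"
  }
  if (anyNA(bits)) bits[is.na(bits)] <- FALSE
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  structure(list(bits = bits, spacing = spacing,
                 voxel_count = sum(bits),
                 voxel_volume = prod(spacing)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$bits)
  cat(sprintf("<binary_mask> %d x %d x %d, %d voxels set (%.1f mm^3)\n",
              d[1], d[2], d[3], x$voxel_count,
              x$voxel_count * x$voxel_volume))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$bits)

# Internal: check that a mask is congruent with a reference grid.
check_congruent <- function(mask, ref) {
  dref <- if (inherits(ref, "ct_volume")) dim(ref$voxels) else dim(ref$bits)
  if (!identical(dim(mask$bits), dref))
    stop("mask shape ", paste(dim(mask$bits), collapse = "x"),
         " does not match grid ", paste(dref, collapse = "x"))
  invisible(TRUE)
}

as_mask <- function(bits, like) {
  spacing <- if (inherits(like, "ct_volume") || inherits(like, "binary_mask"))
    like$spacing else as.numeric(like)
  binary_mask(bits, spacing)
}
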