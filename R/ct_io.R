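#' Load a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI files are read with RNifti; DICOM series directories are read
#' with the built-in reader for uncompressed little-endian series (see
#' [read_dicom_series()]), which applies the rescale slope/intercept and
#' sorts slices superior to inferior. HU values are clamped to the
#' calibrated range \[-1024, 4000\].
#'
#' @param path a `.nii`/`.nii.gz` file or a directory containing one
#'   DICOM series.
#' @param format_hint `"auto"` (default: directories are DICOM, files
#'   NIfTI), `"nifti"` or `"dicom"`.
#' @return a [ct_volume()].
#' @export
load_ct <- function(path, format_hint = c("auto", "nifti", "dicom")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto")
    format_hint <- if (dir.exists(path)) "dicom" else "nifti"
  if (format_hint == "dicom") return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || anyNA(pd[1:3]) || any(pd[1:3] <= 0))
    stop("NIfTI pixdim does not provide three positive spacings")
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  ct_volume(arr, pd[1:3])
}

#' Write a CT volume as NIfTI
#'
#' @param vol a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_ct <- function(vol, path) {
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume")
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Write / read a binary mask as NIfTI
#'
#' Masks are stored as uint8 NIfTI volumes carrying the parent grid's
#' spacing; a save/load round trip reproduces the bits exactly.
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @param parent optional [ct_volume()] the mask must be congruent with.
#' @return `save_mask`: `path` invisibly; `load_mask`: a
#'   [binary_mask()]; `mask_roundtrip`: the reloaded mask.
#' @export
save_mask <- function(mask, path, parent = NULL) {
  if (!inherits(mask, "binary_mask")) stop("`mask` must be a binary_mask")
  if (!is.null(parent)) check_congruent(mask, parent)
  img <- RNifti::asNifti(array(as.integer(mask$bits), dim(mask$bits)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  binary_mask(array(as.numeric(img) != 0, dim(img)[1:3]), pd[1:3])
}

#' @rdname save_mask
#' @export
mask_roundtrip <- function(mask, path, parent = NULL) {
  save_mask(mask, path, parent)
  load_mask(path)
}

# Interpolation weight matrix mapping n_src samples onto n_tgt samples
# while preserving physical extent (cell-centred coordinates).
resize_weights <- function(n_src, n_tgt, nearest = FALSE) {
  scale <- n_src / n_tgt
  src <- (seq_len(n_tgt) - 0.5) * scale + 0.5  # 1-based cell centres
  w <- matrix(0, n_tgt, n_src)
  if (nearest) {
    j <- pmin(pmax(round(src), 1L), n_src)
    w[cbind(seq_len(n_tgt), j)] <- 1
  } else {
    lo <- floor(src)
    frac <- src - lo
    lo <- pmin(pmax(lo, 1L), n_src)
    hi <- pmin(lo + 1L, n_src)
    w[cbind(seq_len(n_tgt), lo)] <- w[cbind(seq_len(n_tgt), lo)] + (1 - frac)
    w[cbind(seq_len(n_tgt), hi)] <- w[cbind(seq_len(n_tgt), hi)] + frac
  }
  w
}

#' Standardize the in-plane grid of a volume
#'
#' Resamples every axial slice to `target x target` pixels, rescaling the
#' in-plane spacing so the physical extent `dim * spacing` is preserved
#' exactly. Slice count and slice spacing are untouched.
#'
#' @param vol a [ct_volume()] with in-plane dimensions >= 32.
#' @param target target in-plane dimension (default 512).
#' @param interpolation `"linear"` (default, for HU volumes) or
#'   `"nearest"` (for label/mask content stored as a volume).
#' @return a [ct_volume()] with in-plane dimensions `target x target`.
#' @export
standardize_grid <- function(vol, target = 512L,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target <- as.integer(target)
  if (is.na(target) || target <= 0L) stop("`target` must be positive")
  d <- dim(vol$voxels)
  if (d[1] < 32L || d[2] < 32L) stop("in-plane dimensions must be >= 32")
  if (d[1] == target && d[2] == target) return(vol)
  nearest <- interpolation == "nearest"
  wr <- resize_weights(d[1], target, nearest)
  wc <- resize_weights(d[2], target, nearest)
  out <- array(0, c(target, target, d[3]))
  for (z in seq_len(d[3]))
    out[, , z] <- wr %*% vol$voxels[, , z] %*% t(wc)
  new_spacing <- c(vol$spacing[1] * d[1] / target,
                   vol$spacing[2] * d[2] / target,
                   vol$spacing[3])
  ct_volume(out, new_spacing, clamp = FALSE)
}
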