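# Synthetic DICOM fixture writer (explicit VR little endian), used to
# exercise the series reader without shipping binary fixtures.

w16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                            endian = "little")
w32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                            endian = "little")

dcm_element <- function(group, elem, vr, value) {
  head <- c(w16(group), w16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), w32(length(value)), value)
  } else {
    c(head, w16(length(value)), value)
  }
}

dcm_string <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

# UI values are null-padded to even length
dcm_ui <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
  r
}

# One axial slice. `pixels` is a matrix of stored values (int16, row =
# image row), written row-major as DICOM requires.
write_dicom_slice <- function(path, pixels, series_uid = "1.2.3.4",
                              instance = 1L, ipp = c(0, 0, 0),
                              pixel_spacing = c(1, 1),
                              slice_thickness = 2.5,
                              slope = 1, intercept = -1024,
                              signed = FALSE) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  px <- writeBin(as.integer(t(pixels)), raw(), size = 2L,
                 endian = "little")
  body <- c(
    dcm_element(0x0002, 0x0010, "UI",
                dcm_ui("1.2.840.10008.1.2.1")),
    dcm_element(0x0020, 0x000E, "UI", dcm_ui(series_uid)),
    dcm_element(0x0020, 0x0013, "IS", dcm_string(as.character(instance))),
    dcm_element(0x0020, 0x0032, "DS",
                dcm_string(paste(ipp, collapse = "\\"))),
    dcm_element(0x0018, 0x0050, "DS",
                dcm_string(as.character(slice_thickness))),
    dcm_element(0x0028, 0x0002, "US", w16(1L)),
    dcm_element(0x0028, 0x0004, "CS", dcm_string("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", w16(rows)),
    dcm_element(0x0028, 0x0011, "US", w16(cols)),
    dcm_element(0x0028, 0x0030, "DS",
                dcm_string(paste(pixel_spacing, collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", w16(16L)),
    dcm_element(0x0028, 0x0101, "US", w16(16L)),
    dcm_element(0x0028, 0x0102, "US", w16(15L)),
    dcm_element(0x0028, 0x0103, "US", w16(if (signed) 1L else 0L)),
    dcm_element(0x0028, 0x1052, "DS", dcm_string(as.character(intercept))),
    dcm_element(0x0028, 0x1053, "DS", dcm_string(as.character(slope))),
    dcm_element(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# A small axial series: one file per slice, superior slice has the
# largest patient z. `stored[[i]]` is the pixel matrix of slice i
# (i = 1 most superior).
write_dicom_series <- function(dir, stored, pixel_spacing = c(0.6, 0.8),
                               dz = 2.5, slope = 1, intercept = -1024,
                               series_uid = "1.2.3.4") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(stored)
  # shuffled file order: the reader must sort by position, not filename
  ord <- rev(seq_len(n))
  for (i in seq_len(n)) {
    z <- (n - i) * dz  # slice 1 (most superior) at the largest z
    write_dicom_slice(file.path(dir, sprintf("sl%03d.dcm", ord[i])),
                      stored[[i]], series_uid = series_uid,
                      instance = i, ipp = c(0, 0, z),
                      pixel_spacing = pixel_spacing,
                      slice_thickness = dz,
                      slope = slope, intercept = intercept)
  }
  invisible(dir)
}
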