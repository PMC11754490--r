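# Minimal DICOM series reader: uncompressed little-endian transfer
# syntaxes (explicit or implicit VR), which covers standard CT axial
# series. Only the tags needed to reconstruct a calibrated HU grid are
# extracted.

DICOM_VRS <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO",
               "LT","OB","OD","OF","OL","OW","PN","SH","SL","SQ","SS",
               "ST","TM","UC","UI","UL","UN","UR","US","UT")

ru16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}
ru32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L,
               endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# Parse one DICOM file, returning the tags of interest as a named list.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- ru16(raw, pos); elem <- ru16(raw, pos + 2L)
    tag <- sprintf("%04X,%04X", group, elem)
    vr_bytes <- raw[(pos + 4L):(pos + 5L)]
    vr <- tryCatch(rawToChar(vr_bytes), error = function(e) "")
    explicit <- vr %in% DICOM_VRS
    if (explicit) {
      if (vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UC",
                    "UR", "UN")) {
        len <- ru32(raw, pos + 8L); vpos <- pos + 12L
      } else {
        len <- ru16(raw, pos + 6L); vpos <- pos + 8L
      }
    } else {
      vr <- "UN"; len <- ru32(raw, pos + 4L); vpos <- pos + 8L
    }
    if (len == 2^32 - 1) {
      # undefined length (sequence): skip to the sequence delimiter
      pat <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0))
      found <- FALSE
      for (i in vpos:(n - 7L)) {
        if (raw[i] == pat[1] && raw[i + 1L] == pat[2] &&
            raw[i + 2L] == pat[3] && raw[i + 3L] == pat[4]) {
          pos <- i + 8L; found <- TRUE; break
        }
      }
      if (!found) break
      next
    }
    if (vpos + len - 1L > n) break
    val_raw <- if (len > 0) raw[vpos:(vpos + len - 1L)] else raw(0)
    keep <- c("0008,0018", "0020,000E", "0020,0013", "0020,0032",
              "0028,0010", "0028,0011", "0028,0030", "0018,0050",
              "0018,0088", "0028,0100", "0028,0103", "0028,1052",
              "0028,1053", "7FE0,0010")
    if (tag %in% keep) out[[tag]] <- list(vr = vr, raw = val_raw)
    pos <- vpos + len
  }
  out
}

dcm_str <- function(tags, tag) {
  v <- tags[[tag]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v$raw[v$raw != as.raw(0)]))
}
dcm_num <- function(tags, tag) {
  s <- dcm_str(tags, tag)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_u16 <- function(tags, tag) {
  v <- tags[[tag]]
  if (is.null(v)) return(NULL)
  readBin(v$raw, "integer", size = 2L, endian = "little", signed = FALSE)
}

#' Read a DICOM series directory into a CT volume
#'
#' Reads every file in `dir` as an uncompressed little-endian DICOM
#' slice, verifies that all slices belong to a single series, applies
#' the rescale slope/intercept to obtain HU, sorts slices superior to
#' inferior (descending patient z), and derives spacing from
#' PixelSpacing plus the inter-slice positions.
#'
#' @param dir directory containing exactly one DICOM series.
#' @return a [ct_volume()].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, parse_dicom_file)

  uids <- unique(unlist(lapply(slices, dcm_str, "0020,000E")))
  if (length(uids) > 1L)
    stop("directory mixes multiple series (SeriesInstanceUID): ",
         paste(uids, collapse = ", "))

  first <- slices[[1]]
  rows <- dcm_u16(first, "0028,0010"); cols <- dcm_u16(first, "0028,0011")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns (0028,0010/0011)")
  ps <- dcm_num(first, "0028,0030")
  if (is.null(ps) || length(ps) != 2L || any(ps <= 0))
    stop("missing or invalid PixelSpacing (0028,0030)")

  zpos <- vapply(slices, function(s) {
    ipp <- dcm_num(s, "0020,0032")
    if (is.null(ipp) || length(ipp) < 3L) NA_real_ else ipp[3]
  }, numeric(1))
  ord <- if (!anyNA(zpos)) {
    order(-zpos)  # superior (largest patient z) first
  } else {
    inst <- vapply(slices, function(s) {
      v <- dcm_num(s, "0020,0013")
      if (is.null(v)) NA_real_ else v[1]
    }, numeric(1))
    if (anyNA(inst))
      stop("cannot order slices: no ImagePositionPatient (0020,0032) ",
           "or InstanceNumber (0020,0013)")
    order(inst)
  }
  slices <- slices[ord]; zpos <- zpos[ord]

  if (length(slices) > 1L && !anyNA(zpos)) {
    dz <- abs(diff(zpos))
    if (max(dz) - min(dz) > 0.01)
      stop("inconsistent slice spacing from ImagePositionPatient: ",
           paste(sprintf("%.3f", unique(round(dz, 3))), collapse = ", "))
    sz <- mean(dz)
  } else {
    sz <- dcm_num(first, "0018,0088")
    if (is.null(sz)) sz <- dcm_num(first, "0018,0050")
    if (is.null(sz) || sz <= 0)
      stop("cannot determine slice spacing: need >= 2 positioned slices, ",
           "SpacingBetweenSlices (0018,0088) or SliceThickness (0018,0050)")
  }

  vox <- array(0, c(cols, rows, length(slices)))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    pd <- s[["7FE0,0010"]]
    if (is.null(pd)) stop("slice ", i, " has no PixelData (7FE0,0010)")
    bits <- dcm_u16(s, "0028,0100"); if (is.null(bits)) bits <- 16L
    if (bits != 16L) stop("only 16-bit PixelData is supported")
    signed <- identical(dcm_u16(s, "0028,0103"), 1L)
    px <- readBin(pd$raw, "integer", n = rows * cols, size = 2L,
                  endian = "little", signed = signed)
    slope <- dcm_num(s, "0028,1053"); if (is.null(slope)) slope <- 1
    inter <- dcm_num(s, "0028,1052"); if (is.null(inter)) inter <- 0
    # PixelData is row-major: the first `cols` samples form the top row
    vox[, , i] <- matrix(px * slope + inter, nrow = cols, ncol = rows)
  }
  # array axis 1 walks columns (PixelSpacing[2]), axis 2 walks rows
  ct_volume(vox, c(ps[2], ps[1], sz))
}
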