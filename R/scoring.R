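#' Agatston density coefficient
#'
#' Maps the peak attenuation of a calcified slice-component to the
#' integer density weight: 130-200 HU -> 1, 200-300 HU -> 2,
#' 300-400 HU -> 3, 400+ HU -> 4. Bins are half-open (`[130,200)`,
#' `[200,300)`, `[300,400)`, `[400,Inf)`), the standard Agatston
#' convention, so exactly 200 HU weighs 2 and exactly 400 HU weighs 4.
#'
#' @param max_hu peak HU of the component; must be >= 130 (calcium below
#'   the candidate threshold cannot form a lesion).
#' @return integer weight in 1..4 (vectorized).
#' @export
density_coefficient <- function(max_hu) {
  if (any(max_hu < 130))
    stop("`max_hu` must be >= 130 (below the calcium threshold)")
  w <- integer(length(max_hu))
  w[max_hu >= 130] <- 1L
  w[max_hu >= 200] <- 2L
  w[max_hu >= 300] <- 3L
  w[max_hu >= 400] <- 4L
  w
}

#' Agatston score of one 2D slice-component
#'
#' Area (mm^2) of the component times the density coefficient of its
#' peak HU.
#'
#' @param area_mm2 in-plane area of the component in mm^2 (>= 0).
#' @param max_hu peak HU of the component (>= 130).
#' @return numeric score (vectorized).
#' @export
slice_component_score <- function(area_mm2, max_hu) {
  if (any(area_mm2 < 0)) stop("`area_mm2` must be non-negative")
  area_mm2 * density_coefficient(max_hu)
}

#' Agatston score of one artery
#'
#' Sums the slice-component scores of every lesion attributed to a
#' single artery: for each lesion, for each axial slice, each 2D
#' connected component contributes area times the coefficient of its own
#' per-slice maximum (the classic per-slice Agatston convention; see
#' [assign_lesions()] for how slice-components are built).
#'
#' @param lesions list of `calcium_lesion` objects sharing one artery
#'   label (an empty list scores 0).
#' @return numeric score.
#' @export
artery_score <- function(lesions) {
  if (length(lesions) == 0L) return(0)
  labs <- unique(vapply(lesions, function(l) l$artery, character(1)))
  if (length(labs) > 1L)
    stop("lesions carry mixed artery labels: ", paste(labs, collapse = ", "))
  sum(vapply(lesions, function(l) {
    sum(slice_component_score(l$slice_components$area_mm2,
                              l$slice_components$max_hu))
  }, numeric(1)))
}

#' CAC-DRS risk category of a total Agatston score
#'
#' Grades per the 5-category Coronary Artery Calcium Data and Reporting
#' System mapping: 0 -> "0", 1-100 -> "I", 101-400 -> "II",
#' 401-1000 -> "III", above 1000 -> "IV". The total is rounded to the
#' nearest integer before binning.
#'
#' @param total_score total coronary Agatston score (>= 0; vectorized).
#' @return character vector of grades in `c("0","I","II","III","IV")`.
#' @export
categorize <- function(total_score) {
  if (any(is.na(total_score)) || any(total_score < 0))
    stop("`total_score` must be non-negative")
  s <- round(total_score)
  g <- character(length(s))
  g[s == 0] <- "0"
  g[s >= 1 & s <= 100] <- "I"
  g[s >= 101 & s <= 400] <- "II"
  g[s >= 401 & s <= 1000] <- "III"
  g[s > 1000] <- "IV"
  g
}

cac_grades <- c("0", "I", "II", "III", "IV")

#' Assemble an Agatston report
#'
#' Collects per-artery scores, the total coronary score (RCA + LAD +
#' LCX; aortic calcium is reported separately and never enters the
#' total), and the CAC-DRS grade of the total.
#'
#' @param lesions list of `calcium_lesion` objects (any mixture of
#'   arteries).
#' @param flags optional character vector of pipeline flags (e.g. that a
#'   fallback reference slice was used).
#' @return object of class `agatston_report` with fields `scores`
#'   (named RCA/LAD/LCX/AORTA), `total`, `grade`, `n_lesions`, `flags`.
#' @export
agatston_report <- function(lesions = list(), flags = character(0)) {
  arteries <- c("RCA", "LAD", "LCX", "AORTA")
  scores <- vapply(arteries, function(a) {
    artery_score(Filter(function(l) l$artery == a, lesions))
  }, numeric(1))
  total <- unname(sum(scores[c("RCA", "LAD", "LCX")]))
  structure(list(scores = scores, total = total,
                 grade = categorize(total),
                 n_lesions = length(lesions), flags = flags),
            class = "agatston_report")
}

#' @export
print.agatston_report <- function(x, ...) {
  cat("Agatston report\n")
  for (a in names(x$scores))
    cat(sprintf("  %-6s %8.1f\n", a, x$scores[[a]]))
  cat(sprintf("  total  %8.1f  (RCA + LAD + LCX; aorta excluded)\n", x$total))
  cat(sprintf("  CAC-DRS category: %s\n", x$grade))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize an Agatston report
#'
#' @param report an [agatston_report()].
#' @param path output `.json` or `.csv` path (format from extension).
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(scores = as.list(report$scores), total = report$total,
           grade = report$grade, n_lesions = report$n_lesions,
           flags = report$flags),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(artery = c(names(report$scores), "TOTAL"),
                     score = c(unname(report$scores), report$total),
                     grade = c(rep("", length(report$scores)), report$grade))
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
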