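# Synthetic non-gated chest CT phantom: HU compartments (air, body soft
# tissue, lung, myocardium, epicardial fat, aortic blood, bone) plus
# calcium lesions with controlled per-slice area and peak HU, so the
# Agatston score of every lesion is known analytically. Organ geometry is
# expressed in fractions of the field of view so one parameterization
# scales across grid sizes; lesions are user-specified in physical units.

ellipse2d <- function(dims, spacing, center, semi) {
  xs <- (seq_len(dims[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dims[2]) - 0.5) * spacing[2]
  outer(((xs - center[1]) / semi[1])^2,
        ((ys - center[2]) / semi[2])^2, "+") <= 1
}

rotate2d <- function(u, angle_deg) {
  th <- angle_deg * pi / 180
  c(cos(th) * u[1] - sin(th) * u[2],
    sin(th) * u[1] + cos(th) * u[2])
}

#' Specify a synthetic chest CT phantom
#'
#' Defines the geometry, tissue HU values, calcium lesions and noise of
#' a digital chest phantom. Organ geometry scales with the field of
#' view; lesions are given in physical units (in-plane area in mm^2 per
#' slice, slice span, peak and plateau HU, artery territory).
#'
#' Each lesion is a list with fields `artery` (`"RCA"`, `"LAD"`,
#' `"LCX"` or `"AORTA"`), `area_mm2`, `n_slices`, `slice` (centre slice
#' index), `peak_hu` (>= 130; placed in a single voxel at the lesion
#' centre), `plateau_hu` (all other lesion voxels) and, for coronary
#' lesions, `angle_deg`: the angular position on the epicardial shell
#' measured from the heart-centre-to-aorta axis (counter-clockwise).
#'
#' @param dims grid dimensions, default `c(256, 256, 60)`.
#' @param spacing voxel spacing in mm, default `c(0.7, 0.7, 2.5)`.
#' @param lesions list of lesion specs, or `NULL` for the default three
#'   coronary lesions (one per artery).
#' @param noise_sd additive Gaussian HU noise (0 = noise free).
#' @param seed integer seed controlling the noise.
#' @param fat_hu,aorta_hu,myocardium_hu,bone_hu tissue HU values.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(256L, 256L, 60L),
                         spacing = c(0.7, 0.7, 2.5),
                         lesions = NULL,
                         noise_sd = 0, seed = 0L,
                         fat_hu = -100, aorta_hu = 55,
                         myocardium_hu = 40, bone_hu = 1000) {
  dims <- as.integer(dims)
  fov <- dims * spacing
  fx <- fov[1]; fy <- fov[2]; fz <- fov[3]
  geom <- list(
    body = list(center = c(0.5 * fx, 0.5 * fy),
                semi = c(0.445 * fx, 0.363 * fy), hu = 40),
    lung = list(center = c(0.5 * fx, 0.5 * fy),
                semi = c(0.38 * fx, 0.30 * fy), hu = -800),
    heart = list(center = c(0.5 * fx, 0.54 * fy, 0.60 * fz),
                 semi = c(0.167 * fx, 0.145 * fy, 0.253 * fz),
                 hu = myocardium_hu),
    fat = list(thickness = 0.028 * fx, hu = fat_hu),
    aorta = list(center = c(0.625 * fx, 0.335 * fy),
                 radius = 0.067 * fx,
                 ellipse_semi = c(0.10 * fx, 0.056 * fy),
                 circular = seq_len(round(0.10 * dims[3])),
                 elliptical = (round(0.10 * dims[3]) + 1):round(0.20 * dims[3]),
                 semi_elliptical = (round(0.20 * dims[3]) + 1):round(0.28 * dims[3]),
                 hu = aorta_hu),
    spine = list(center = c(0.5 * fx, 0.78 * fy),
                 radius = 0.05 * fx, hu = bone_hu),
    ribs = list(angles = c(20, 160, 200, 340),
                ring = c(0.41 * fx, 0.33 * fy),
                radius = 0.02 * fx, hu = 700),
    flecks = list(offsets = c(-35, 35),  # degrees around spine, from +x
                  gap = 1.5, radius = 0.011 * fx, hu = 700,
                  slices = round(0.5 * dims[3]) + 0:1)
  )
  if (is.null(lesions)) {
    rho <- 0.75 * geom$fat$thickness / 2
    area <- round(pi * rho^2, 1)
    lesions <- list(
      list(artery = "RCA", area_mm2 = area, n_slices = 2L,
           slice = round(0.58 * dims[3]), peak_hu = 450, plateau_hu = 300,
           angle_deg = -10),
      list(artery = "LAD", area_mm2 = area, n_slices = 2L,
           slice = round(0.62 * dims[3]), peak_hu = 250, plateau_hu = 200,
           angle_deg = 140),
      list(artery = "LCX", area_mm2 = area, n_slices = 1L,
           slice = round(0.60 * dims[3]), peak_hu = 800, plateau_hu = 300,
           angle_deg = -130))
  }
  for (i in seq_along(lesions)) {
    l <- lesions[[i]]
    if (!l$artery %in% c("RCA", "LAD", "LCX", "AORTA"))
      stop("lesion ", i, ": unknown artery ", l$artery)
    if (l$peak_hu < 130) stop("lesion ", i, ": peak HU must be >= 130")
    if (l$area_mm2 <= 0) stop("lesion ", i, ": area must be positive")
  }
  if (geom$fat$hu < -190 || geom$fat$hu > -30)
    stop("fat HU must lie in the adipose window [-190, -30]")
  structure(list(dims = dims, spacing = spacing, geom = geom,
                 lesions = lesions, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 first_elliptical_slice = geom$aorta$elliptical[1]),
            class = "phantom_spec")
}

# In-plane radius of an axis-aligned ellipsoid cross-section at height
# z_mm along unit direction u, measured from its centre.
ellipsoid_radius <- function(center, semi, z_mm, u) {
  f <- 1 - ((z_mm - center[3]) / semi[3])^2
  if (f <= 0) return(0)
  sqrt(f) / sqrt((u[1] / semi[1])^2 + (u[2] / semi[2])^2)
}

# Aorta cross-section mask for one slice (or NULL when absent).
aorta_slice_mask <- function(spec, z) {
  a <- spec$geom$aorta
  if (z %in% a$circular) {
    ellipse2d(spec$dims, spec$spacing, a$center, rep(a$radius, 2))
  } else if (z %in% a$elliptical) {
    ellipse2d(spec$dims, spec$spacing, a$center, a$ellipse_semi)
  } else if (z %in% a$semi_elliptical) {
    ell <- ellipse2d(spec$dims, spec$spacing, a$center, a$ellipse_semi)
    bite <- ellipse2d(spec$dims, spec$spacing,
                      a$center - c(0.55 * a$ellipse_semi[1], 0),
                      rep(0.9 * a$ellipse_semi[2], 2))
    ell & !bite
  } else NULL
}

#' Generate a phantom volume and its ground truth
#'
#' Rasterizes the compartments of a [phantom_spec()], adds seeded
#' Gaussian noise, and returns the volume together with exact truth:
#' organ masks, bone mask, per-lesion voxel sets with their noise-free
#' HU, the first-elliptical aorta slice, and the analytic per-artery
#' Agatston scores from [expected_agatston()].
#'
#' Calcium lesions that collide with another compartment (another
#' lesion, bone, the myocardium, or falling outside the heart) raise an
#' error naming the colliding pair.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [ct_volume()]) and `truth`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  dims <- spec$dims; spacing <- spec$spacing; g <- spec$geom
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  zc_mm <- (seq_len(nz) - 0.5) * spacing[3]

  body2d <- ellipse2d(dims, spacing, g$body$center, g$body$semi)
  lung2d <- ellipse2d(dims, spacing, g$lung$center, g$lung$semi)
  spine2d <- ellipse2d(dims, spacing, g$spine$center, rep(g$spine$radius, 2))
  ribs2d <- matrix(FALSE, nx, ny)
  for (ang in g$ribs$angles) {
    cen <- g$body$center + c(g$ribs$ring[1] * cos(ang * pi / 180),
                             g$ribs$ring[2] * sin(ang * pi / 180))
    ribs2d <- ribs2d | ellipse2d(dims, spacing, cen, rep(g$ribs$radius, 2))
  }
  base <- matrix(-1000, nx, ny)
  base[body2d] <- g$body$hu
  base[lung2d] <- g$lung$hu
  base[spine2d] <- g$spine$hu
  base[ribs2d] <- g$ribs$hu

  vox <- array(base, c(nx, ny, nz))
  heart_bits <- array(FALSE, c(nx, ny, nz))
  aorta_bits <- array(FALSE, c(nx, ny, nz))
  fat_bits <- array(FALSE, c(nx, ny, nz))
  bone_bits <- array(spine2d | ribs2d, c(nx, ny, nz))

  # bone flecks adjacent to the spine (merged away by the bone filter)
  for (k in seq_along(g$flecks$offsets)) {
    ang <- g$flecks$offsets[k]
    dist <- g$spine$radius + g$flecks$gap + g$flecks$radius
    cen <- g$spine$center + dist * c(cos(ang * pi / 180), sin(ang * pi / 180))
    fl2d <- ellipse2d(dims, spacing, cen, rep(g$flecks$radius, 2))
    for (z in g$flecks$slices) {
      sl <- vox[, , z]; sl[fl2d] <- g$flecks$hu; vox[, , z] <- sl
      bone_bits[, , z] <- bone_bits[, , z] | fl2d
    }
  }

  h <- g$heart
  outer_semi <- h$semi + g$fat$thickness
  for (z in seq_len(nz)) {
    am <- aorta_slice_mask(spec, z)
    sl <- vox[, , z]
    if (!is.null(am) && any(am)) {
      sl[am] <- g$aorta$hu
      aorta_bits[, , z] <- am
    }
    fo <- 1 - ((zc_mm[z] - h$center[3]) / outer_semi[3])^2
    if (fo > 0) {
      om <- ellipse2d(dims, spacing, h$center[1:2], sqrt(fo) * outer_semi[1:2])
      sl[om] <- g$fat$hu
      fi <- 1 - ((zc_mm[z] - h$center[3]) / h$semi[3])^2
      im <- if (fi > 0)
        ellipse2d(dims, spacing, h$center[1:2], sqrt(fi) * h$semi[1:2])
      else matrix(FALSE, nx, ny)
      sl[im] <- h$hu
      heart_bits[, , z] <- om
      fat_bits[, , z] <- om & !im
    }
    vox[, , z] <- sl
  }

  # lesions
  u0 <- g$aorta$center - h$center[1:2]
  u0 <- u0 / sqrt(sum(u0^2))
  lesion_truth <- vector("list", length(spec$lesions))
  lesion_all <- array(FALSE, c(nx, ny, nz))
  inner_bits <- heart_bits & !fat_bits
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    rho <- sqrt(l$area_mm2 / pi)
    z0 <- l$slice - (l$n_slices - 1L) %/% 2L
    zr <- z0:(z0 + l$n_slices - 1L)
    if (any(zr < 1L | zr > nz)) stop("lesion ", i, ": slice span outside grid")
    if (l$artery == "AORTA") {
      cen <- g$aorta$center
      if (!all(vapply(zr, function(z) !is.null(aorta_slice_mask(spec, z)),
                      logical(1))))
        stop("lesion ", i, " (AORTA) placed on slices without aorta")
    } else {
      u <- rotate2d(u0, l$angle_deg)
      zmid <- zc_mm[l$slice]
      r_in <- ellipsoid_radius(h$center, h$semi, zmid, u)
      r_out <- ellipsoid_radius(h$center, outer_semi, zmid, u)
      if (r_out <= 0) stop("lesion ", i, ": slice outside the heart")
      cen <- h$center[1:2] + u * (r_in + r_out) / 2
    }
    d2d <- ellipse2d(dims, spacing, cen, rep(rho, 2))
    if (!any(d2d)) stop("lesion ", i, ": area too small to rasterize")
    idx2d <- which(d2d)
    # peak voxel: nearest voxel to the lesion centre, centre slice
    xs <- (seq_len(nx) - 0.5) * spacing[1]
    ys <- (seq_len(ny) - 0.5) * spacing[2]
    ij <- arrayInd(idx2d, c(nx, ny))
    dd <- (xs[ij[, 1]] - cen[1])^2 + (ys[ij[, 2]] - cen[2])^2
    peak2d <- idx2d[which.min(dd)]

    idx <- integer(0); hu <- numeric(0); slice_of <- integer(0)
    for (z in zr) {
      lin <- idx2d + (z - 1L) * nx * ny
      hz <- rep(l$plateau_hu, length(lin))
      if (z == l$slice) hz[lin == peak2d + (z - 1L) * nx * ny] <- l$peak_hu
      idx <- c(idx, lin); hu <- c(hu, hz)
      slice_of <- c(slice_of, rep(z, length(lin)))
    }
    if (any(lesion_all[idx]))
      stop("overlapping compartments: lesion ", i, " and an earlier lesion")
    if (any(bone_bits[idx]))
      stop("overlapping compartments: lesion ", i, " and bone")
    if (l$artery == "AORTA") {
      if (!all(aorta_bits[idx]))
        stop("overlapping compartments: lesion ", i,
             " (AORTA) extends outside the aorta")
    } else {
      if (any(aorta_bits[idx]))
        stop("overlapping compartments: lesion ", i, " and the aorta")
      if (any(inner_bits[idx]) || !all(heart_bits[idx]))
        stop("overlapping compartments: lesion ", i, " (", l$artery,
             ") collides with the myocardium or extends outside the heart")
      fat_bits[idx] <- FALSE
    }
    lesion_all[idx] <- TRUE
    vox[idx] <- hu
    lesion_truth[[i]] <- list(artery = l$artery, idx = idx, hu = hu,
                              slice = slice_of,
                              area_mm2 = l$area_mm2,
                              peak_hu = l$peak_hu, plateau_hu = l$plateau_hu)
  }

  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(spec$seed)
    vox <- vox + rnorm(length(vox), 0, spec$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  vox <- round(vox)

  truth <- list(
    heart = binary_mask(heart_bits, spacing),
    aorta = binary_mask(aorta_bits, spacing),
    fat = binary_mask(fat_bits, spacing),
    bone = binary_mask(bone_bits, spacing),
    lesions = lesion_truth,
    first_elliptical_slice = spec$first_elliptical_slice,
    spec = spec)
  truth$expected <- expected_agatston(truth)
  list(volume = ct_volume(vox, spacing, clamp = FALSE), truth = truth)
}

#' Analytic Agatston scores of phantom ground truth
#'
#' The independent oracle for the scoring pipeline: walks the truth
#' lesion voxel sets (noise-free HU values) and accumulates, per artery,
#' area (mm^2) times the density coefficient of the per-slice maximum,
#' counting only voxels at or above `hu_min`.
#'
#' @param truth the `truth` element returned by [generate_phantom()].
#' @param hu_min candidate threshold, default 130 HU.
#' @return list with per-artery scores (`RCA`, `LAD`, `LCX`, `AORTA`),
#'   `total` (coronary arteries only; the aorta is reported separately)
#'   and `grade` (CAC-DRS category of the total).
#' @export
expected_agatston <- function(truth, hu_min = 130) {
  spacing <- truth$heart$spacing
  pix <- spacing[1] * spacing[2]
  scores <- c(RCA = 0, LAD = 0, LCX = 0, AORTA = 0)
  for (l in truth$lesions) {
    keep <- l$hu >= hu_min
    if (!any(keep)) next
    for (z in unique(l$slice[keep])) {
      sel <- keep & l$slice == z
      area <- sum(sel) * pix
      scores[l$artery] <- scores[l$artery] +
        area * density_coefficient(max(l$hu[sel]))
    }
  }
  total <- unname(scores["RCA"] + scores["LAD"] + scores["LCX"])
  list(RCA = unname(scores["RCA"]), LAD = unname(scores["LAD"]),
       LCX = unname(scores["LCX"]), AORTA = unname(scores["AORTA"]),
       total = total, grade = categorize(total))
}

#' Randomized phantom specification
#'
#' Draws a phantom with randomized lesion content under the default
#' geometry: each coronary artery independently carries a lesion with
#' probability `p_lesion` (area 6-12 mm^2, peak 200-900 HU, plateau
#' 140-300 HU, 1-3 slices, angle jittered +/-25 degrees around the
#' territory's canonical position), and an aortic lesion appears with
#' probability `p_aorta`. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param dims,spacing grid geometry, passed to [phantom_spec()].
#' @param noise_sd additive HU noise.
#' @param p_lesion,p_aorta lesion inclusion probabilities.
#' @param area_range lesion in-plane area range in mm^2; the default
#'   suits the default grid's epicardial shell.
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, dims = c(256L, 256L, 60L),
                                spacing = c(0.7, 0.7, 2.5),
                                noise_sd = 0,
                                p_lesion = 0.8, p_aorta = 0.3,
                                area_range = c(6, 12)) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  nz <- dims[3]
  canonical <- c(RCA = -10, LAD = 140, LCX = -130)
  slices <- round(c(0.56, 0.62, 0.59) * nz)
  lesions <- list()
  for (k in seq_along(canonical)) {
    if (runif(1) > p_lesion) next
    peak <- round(runif(1, 200, 900))
    lesions[[length(lesions) + 1L]] <- list(
      artery = names(canonical)[k],
      area_mm2 = round(runif(1, area_range[1], area_range[2]), 1),
      n_slices = sample(1:3, 1),
      slice = slices[k] + sample(-2:2, 1),
      peak_hu = peak,
      plateau_hu = round(runif(1, 140, min(300, peak))),
      angle_deg = canonical[[k]] + runif(1, -25, 25))
  }
  if (runif(1) < p_aorta) {
    peak <- round(runif(1, 200, 900))
    lesions[[length(lesions) + 1L]] <- list(
      artery = "AORTA",
      area_mm2 = round(runif(1, area_range[1], area_range[2]), 1),
      n_slices = sample(1:2, 1),
      slice = sample(3:(round(0.18 * nz)), 1),
      peak_hu = peak,
      plateau_hu = round(runif(1, 140, min(300, peak))))
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  phantom_spec(dims = dims, spacing = spacing, lesions = lesions,
               noise_sd = noise_sd, seed = seed)
}
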