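#' Pipeline configuration
#'
#' Collects every tunable of the scoring pipeline in one serializable
#' list, validated up front so a run is reproducible from its logged
#' config. Defaults carry the shipped operating point: candidate
#' threshold 130 HU and bone-merge component size 10000 voxels.
#'
#' @param target_in_plane in-plane standardization target; `NA` (the
#'   default) keeps the native grid, 512 matches the common clinical
#'   format.
#' @param smooth_iter,smooth_contrast_scale,smooth_step anisotropic
#'   diffusion parameters for the segmentation input (`smooth_iter = 0`
#'   disables smoothing). Scoring always reads raw HU.
#' @param backend `"reference"` or `"files"`.
#' @param soft_window,body_hu_min,close_mm reference-backend parameters.
#' @param fat_hu_range,fat_shell_mm epicardial fat window and shell.
#' @param corridor_dilate_mm,corridor_erode_mm coronary corridor closing.
#' @param offset_mm reference-to-localization slice offset in mm.
#' @param sector_rca,sector_lad angular sectors in degrees
#'   (counter-clockwise from the heart-to-aorta axis); LCX takes the
#'   remainder.
#' @param hu_min,noise_min_voxels,noise_min_peak_hu,bone_merge_voxels,bone_dilate_radius,connectivity,connectivity_2d
#'   calcium cascade parameters, see [calcium_params()].
#' @param allow_reference_fallback when no elliptical aorta slice is
#'   found, fall back to the maximum-area slice (flagged in the report)
#'   instead of aborting.
#' @param seed top-level seed recorded with the run.
#' @return a validated list of class `cac_config`.
#' @export
cac_config <- function(target_in_plane = NA_integer_,
                       smooth_iter = 0L, smooth_contrast_scale = 30,
                       smooth_step = 0.2,
                       backend = "reference",
                       soft_window = c(-300, 300), body_hu_min = -500,
                       close_mm = 3,
                       fat_hu_range = c(-190, -30), fat_shell_mm = 10,
                       corridor_dilate_mm = 5, corridor_erode_mm = 5,
                       offset_mm = 10,
                       sector_rca = c(-100, 80), sector_lad = c(80, 200),
                       hu_min = 130, noise_min_voxels = 3L,
                       noise_min_peak_hu = 160,
                       bone_merge_voxels = 10000L, bone_dilate_radius = 3L,
                       connectivity = 26L, connectivity_2d = 8L,
                       allow_reference_fallback = TRUE, seed = 0L) {
  cfg <- list(target_in_plane = target_in_plane,
              smooth_iter = as.integer(smooth_iter),
              smooth_contrast_scale = smooth_contrast_scale,
              smooth_step = smooth_step,
              backend = backend,
              soft_window = soft_window, body_hu_min = body_hu_min,
              close_mm = close_mm,
              fat_hu_range = fat_hu_range, fat_shell_mm = fat_shell_mm,
              corridor_dilate_mm = corridor_dilate_mm,
              corridor_erode_mm = corridor_erode_mm,
              offset_mm = offset_mm,
              sector_rca = sector_rca, sector_lad = sector_lad,
              hu_min = hu_min,
              noise_min_voxels = as.integer(noise_min_voxels),
              noise_min_peak_hu = noise_min_peak_hu,
              bone_merge_voxels = as.integer(bone_merge_voxels),
              bone_dilate_radius = as.integer(bone_dilate_radius),
              connectivity = as.integer(connectivity),
              connectivity_2d = as.integer(connectivity_2d),
              allow_reference_fallback = isTRUE(allow_reference_fallback),
              seed = as.integer(seed))
  # validate against the module invariants before any computation
  calcium_params(cfg$hu_min, cfg$noise_min_voxels, cfg$noise_min_peak_hu,
                 cfg$bone_merge_voxels, cfg$bone_dilate_radius,
                 cfg$connectivity, cfg$connectivity_2d)
  if (cfg$smooth_iter > 0) {
    if (cfg$smooth_contrast_scale <= 0) stop("smooth_contrast_scale must be > 0")
    if (cfg$smooth_step <= 0 || cfg$smooth_step > 0.25)
      stop("smooth_step must be in (0, 0.25]")
  }
  if (!is.na(cfg$target_in_plane) && cfg$target_in_plane <= 0)
    stop("target_in_plane must be positive or NA")
  if (cfg$offset_mm < 0) stop("offset_mm must be >= 0")
  if (cfg$fat_shell_mm <= 0) stop("fat_shell_mm must be > 0")
  structure(cfg, class = "cac_config")
}

stage_msg <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full scoring pipeline on one volume
#'
#' Executes the four stages in order - (1) multi-organ segmentation,
#' (2) coronary artery region segmentation, (3) calcium segmentation,
#' (4) Agatston scoring - and returns the report with all intermediate
#' artifacts. Identical inputs and config give identical outputs.
#'
#' @param volume a [ct_volume()] or a path accepted by [load_ct()].
#' @param config a [cac_config()].
#' @param masks optional [organ_mask_set()] injected in place of the
#'   segmentation backend (stage isolation / external models).
#' @param backend optional backend list (see [reference_backend()]);
#'   defaults to the backend named in `config`.
#' @param out_dir optional directory: masks (NIfTI), lesion table
#'   (CSV), report (JSON + CSV) and resolved config (JSON) are written
#'   there.
#' @param verbose log one line per stage with voxel counts.
#' @return list of class `cac_result`: `report` ([agatston_report()]),
#'   `lesions`, `masks`, `region_map`, `profile`, `config`.
#' @export
run_pipeline <- function(volume, config = cac_config(), masks = NULL,
                         backend = NULL, out_dir = NULL, verbose = FALSE) {
  if (is.character(volume)) volume <- load_ct(volume)
  if (!inherits(volume, "ct_volume")) stop("`volume` must be a ct_volume")

  vol <- volume
  if (!is.na(config$target_in_plane))
    vol <- standardize_grid(vol, config$target_in_plane)
  seg_input <- if (config$smooth_iter > 0)
    anisotropic_smooth(vol, config$smooth_iter,
                       config$smooth_contrast_scale, config$smooth_step)
  else vol

  # stage 1: multi-organ segmentation
  if (is.null(masks)) {
    if (is.null(backend)) {
      if (config$backend != "reference")
        stop("stage segmentation: backend '", config$backend,
             "' requires an explicit `backend` argument (e.g. file_backend)")
      backend <- reference_backend(soft_window = config$soft_window,
                                   body_hu_min = config$body_hu_min,
                                   close_mm = config$close_mm,
                                   fat_hu_range = config$fat_hu_range,
                                   fat_shell_mm = config$fat_shell_mm)
    }
    masks <- tryCatch(backend$segment(seg_input), error = function(e)
      stop("stage segmentation: ", conditionMessage(e), call. = FALSE))
  }
  stage_msg(verbose, "segmentation", "heart %d, aorta %d, fat %d voxels",
            masks$heart$voxel_count, masks$aorta$voxel_count,
            masks$epicardial_fat$voxel_count)

  # stage 2: coronary artery region segmentation
  flags <- character(0)
  profile <- aorta_shape_profile(masks$aorta)
  ref <- tryCatch(
    find_reference_slice(profile, vol$spacing[3], config$offset_mm,
                         allow_fallback = config$allow_reference_fallback),
    error = function(e)
      stop("stage region_split: ", conditionMessage(e), call. = FALSE))
  if (ref$fallback_used)
    flags <- c(flags, "reference slice fallback: maximum-area aorta slice")
  corridor <- coronary_corridor(masks$epicardial_fat,
                                config$corridor_dilate_mm,
                                config$corridor_erode_mm)
  region_map <- split_heart_regions(
    masks$heart, masks$aorta, corridor, ref,
    sectors = list(rca = config$sector_rca, lad = config$sector_lad))
  stage_msg(verbose, "region_split",
            "reference slice %d, localization %d, corridor %d voxels",
            ref$reference, ref$localization, corridor$voxel_count)

  # stage 3: calcium segmentation cascade (raw HU, never smoothed)
  params <- calcium_params(config$hu_min, config$noise_min_voxels,
                           config$noise_min_peak_hu,
                           config$bone_merge_voxels,
                           config$bone_dilate_radius,
                           config$connectivity, config$connectivity_2d)
  cand <- candidate_mask(vol, params$hu_min)
  denoised <- suppress_noise(cand, vol, params)
  deboned <- remove_bone(denoised, vol, params)
  recovered <- recover_components(deboned, cand, params)
  cardiac <- as_mask(masks$heart$bits | masks$aorta$bits, vol)
  lesions <- assign_lesions(recovered, cardiac, region_map, vol, params)
  stage_msg(verbose, "calcium",
            "candidates %d -> denoised %d -> deboned %d -> recovered %d; %d lesions",
            cand$voxel_count, denoised$voxel_count, deboned$voxel_count,
            recovered$voxel_count, length(lesions))

  # stage 4: Agatston scoring + CAC-DRS grading
  report <- agatston_report(lesions, flags)
  stage_msg(verbose, "scoring", "total %.1f, grade %s",
            report$total, report$grade)

  result <- structure(list(report = report, lesions = lesions,
                           masks = masks, region_map = region_map,
                           profile = profile, config = config),
                      class = "cac_result")
  if (!is.null(out_dir)) write_result(result, vol, recovered, out_dir)
  result
}

write_result <- function(result, vol, calcium_mask, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_mask(result$masks$heart, file.path(out_dir, "heart_mask.nii.gz"))
  save_mask(result$masks$aorta, file.path(out_dir, "aorta_mask.nii.gz"))
  save_mask(result$masks$epicardial_fat,
            file.path(out_dir, "fat_mask.nii.gz"))
  save_mask(calcium_mask, file.path(out_dir, "calcium_mask.nii.gz"))
  lbl <- RNifti::asNifti(result$region_map$labels)
  RNifti::pixdim(lbl) <- result$region_map$spacing
  RNifti::writeNifti(lbl, file.path(out_dir, "region_map.nii.gz"),
                     datatype = "uint8")
  write.csv(lesion_table(result$lesions),
            file.path(out_dir, "lesions.csv"), row.names = FALSE)
  save_report(result$report, file.path(out_dir, "report.json"))
  save_report(result$report, file.path(out_dir, "report.csv"))
  jsonlite::write_json(unclass(result$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.cac_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Evaluate predicted against reference scores for a cohort
#'
#' Reads paired per-subject scores (or grades), derives CAC-DRS grades
#' via [categorize()] where only raw scores are given, and computes the
#' full agreement report: confusion matrix, Cohen's kappa with CI,
#' exact/within-one agreement, per-grade diagnostics, presence/absence
#' sensitivity and specificity, and the Pearson correlation of raw
#' scores.
#'
#' @param pairs a data.frame or CSV path with columns `reference` and
#'   `predicted` (raw Agatston totals) and/or `reference_grade`,
#'   `predicted_grade`.
#' @param out_path optional JSON output path.
#' @return list of class `eval_report`.
#' @export
evaluate_pairs <- function(pairs, out_path = NULL) {
  if (is.character(pairs)) {
    if (!file.exists(pairs)) stop("no such file: ", pairs)
    pairs <- read.csv(pairs, stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0L) stop("no subjects in the pairs table")
  have_scores <- all(c("reference", "predicted") %in% names(pairs))
  have_grades <- all(c("reference_grade", "predicted_grade") %in% names(pairs))
  if (!have_scores && !have_grades)
    stop("need columns reference/predicted or reference_grade/predicted_grade")
  if (have_scores) {
    bad <- which(is.na(pairs$reference) | is.na(pairs$predicted) |
                 pairs$reference < 0 | pairs$predicted < 0)
    if (length(bad) > 0L)
      stop("malformed score rows (missing or negative): ",
           paste(bad, collapse = ", "))
  }
  ref_g <- if (have_grades) pairs$reference_grade
           else categorize(pairs$reference)
  prd_g <- if (have_grades) pairs$predicted_grade
           else categorize(pairs$predicted)
  cm <- confusion(ref_g, prd_g)
  kap <- cohen_kappa(cm)
  report <- structure(list(
    n = sum(cm), confusion = cm, kappa = kap,
    agreement = agreement_summary(cm),
    per_category = per_category_metrics(cm),
    presence = if (have_scores)
      presence_metrics(pairs$reference, pairs$predicted)
    else list(sensitivity = NA_real_, specificity = NA_real_),
    pearson = if (have_scores) cor(pairs$reference, pairs$predicted)
    else NA_real_), class = "eval_report")
  if (!is.null(out_path)) {
    jsonlite::write_json(
      list(n = report$n,
           confusion = as.data.frame.matrix(unclass(report$confusion)),
           kappa = report$kappa, agreement = report$agreement,
           per_category = report$per_category,
           presence = report$presence, pearson = report$pearson),
      out_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d subjects\n", x$n))
  cat(sprintf("  kappa %.3f (95%% CI %.3f-%.3f)\n",
              x$kappa$kappa, x$kappa$ci_low, x$kappa$ci_high))
  cat(sprintf("  exact agreement %.1f%%, within one category %.1f%%\n",
              100 * x$agreement$exact, 100 * x$agreement$within_one))
  if (!is.na(x$presence$sensitivity))
    cat(sprintf("  presence sensitivity %.2f, specificity %.2f\n",
                x$presence$sensitivity, x$presence$specificity))
  invisible(x)
}
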