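# Shared fixtures. The mid-size phantom (192x192x48) is generated once
# per test run and reused by the segmentation, region-split and pipeline
# tests; lesion areas are scaled to its thinner fat shell.

.fixtures <- new.env()

small_dims <- c(192L, 192L, 48L)

small_lesions <- function() {
  list(
    list(artery = "RCA", area_mm2 = 6, n_slices = 2L, slice = 28L,
         peak_hu = 450, plateau_hu = 300, angle_deg = -10),
    list(artery = "LAD", area_mm2 = 6, n_slices = 2L, slice = 30L,
         peak_hu = 250, plateau_hu = 200, angle_deg = 140),
    list(artery = "LCX", area_mm2 = 5, n_slices = 1L, slice = 29L,
         peak_hu = 800, plateau_hu = 300, angle_deg = -130))
}

shared_phantom <- function() {
  if (is.null(.fixtures$ph))
    .fixtures$ph <- generate_phantom(
      phantom_spec(dims = small_dims, lesions = small_lesions()))
  .fixtures$ph
}

native_config <- function(...) cac_config(target_in_plane = NA, ...)

# tolerance for comparing a pipeline score against the analytic oracle:
# +/- one voxel-area per slice-component at the largest coefficient
raster_tol <- function(truth, spacing = truth$heart$spacing) {
  n_comp <- sum(vapply(truth$lesions,
                       function(l) length(unique(l$slice)), integer(1)))
  max(1, n_comp) * spacing[1] * spacing[2] * 4
}
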