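# Shared fixtures: small synthetic cohorts and ROIs built in code.

small_gm_cohort <- function(seed = 1, grid = c(16, 16, 16), n_per_cell = NULL,
                            patterns = list(), couplings = list(), ...) {
  spec <- if (is.null(n_per_cell)) abide_cohort_spec(seed = seed)
  else cohort_spec(n_per_cell, seed = seed)
  generate_gm_cohort(spec, grid_shape = grid, patterns = patterns,
                     couplings = couplings, ...)
}

# cohort restricted to the ASD subjects, with the matching table rows
asd_subset <- function(gen) {
  keep <- gen$table$group == "ASD"
  sub <- gen$cohort
  sub$data <- sub$data[, keep, drop = FALSE]
  sub$subject_ids <- sub$subject_ids[keep]
  list(cohort = sub, table = droplevels(gen$table[keep, ]))
}

# center-of-grid sphere ROI helper
center_sphere <- function(grid = c(32, 32, 32), voxel_size = c(3, 3, 3),
                          center_vox = round(grid / 2), radius_mm = 8,
                          mask = NULL) {
  if (is.null(mask)) mask <- ellipsoid_mask(grid)
  aff <- dimorphMVPA:::.default_affine(dim(mask), voxel_size)
  ctr <- as.numeric(voxel_to_world(aff, matrix(center_vox, 1)))
  sphere_roi_voxels(ctr, radius_mm, mask, aff)
}
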