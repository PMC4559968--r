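# Synthetic gray-matter cohort generator: baseline maps plus implanted
# group/sex patterns, age and site nuisance structure, ROI-symptom
# couplings, Gaussian noise, and VBM-order smoothing (inject, then smooth).

#' Specify an implanted multivoxel pattern
#'
#' Describes a discriminative gray-matter pattern to implant into a
#' synthetic cohort. `"mean-shift"` adds `+amplitude/2` to the first level
#' of the contrast factor and `-amplitude/2` to the second at every ROI
#' voxel (a univariate-visible difference). `"covariance-pattern"` splits
#' the ROI into two contiguous half-blocks and adds a per-subject random
#' sign `z = +/-amplitude` with equal signs on the two halves in one class
#' and opposite signs in the other: per-voxel marginal distributions are
#' identical across classes (univariate tests are blind to it) while the
#' half-to-half correlation flips sign, which a multivoxel classifier can
#' exploit.
#'
#' @param roi_voxels k x 3 matrix of 1-based voxel indices.
#' @param effect_type `"mean-shift"` or `"covariance-pattern"`.
#' @param amplitude effect amplitude in GM units (>= 0).
#' @param contrast name of the factor whose levels the pattern separates
#'   (`"sex"` or `"group"`).
#' @param within optional cell restriction: only subjects of this
#'   diagnostic group carry the pattern (e.g. `"ASD"`); `NULL` = all.
#' @return an object of class `pattern_spec`.
#' @export
pattern_spec <- function(roi_voxels,
                         effect_type = c("mean-shift", "covariance-pattern"),
                         amplitude, contrast = "sex", within = NULL) {
  effect_type <- match.arg(effect_type)
  roi_voxels <- matrix(as.integer(roi_voxels), ncol = 3)
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(roi_voxels = roi_voxels, effect_type = effect_type,
                 amplitude = amplitude, contrast = contrast, within = within),
            class = "pattern_spec")
}

#' Specify an ROI-symptom coupling
#'
#' Imposes a target correlation between the mean gray-matter value of an
#' ROI and one symptom-domain score, within one `group.sex` subgroup only.
#' The generator calibrates the coupling slope against the realized
#' nuisance + noise variability of the ROI mean so the induced population
#' correlation matches `coupling_r`.
#'
#' @param roi_voxels k x 3 matrix of 1-based voxel indices.
#' @param target_domain one of `adi_social`, `adi_comm`, `adi_rrb`.
#' @param coupling_r target correlation, |r| <= 0.99.
#' @param apply_to subgroup label, e.g. `"ASD.F"`.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(roi_voxels, target_domain, coupling_r,
                          apply_to = "ASD.F") {
  if (!target_domain %in% .DOMAINS) stop("unknown domain: ", target_domain)
  if (abs(coupling_r) > 0.99)
    stop("|coupling_r| must be <= 0.99 (the calibrated slope diverges at 1)")
  if (!grepl("^(ASD|TD)\\.(F|M)$", apply_to))
    stop("apply_to must name a group.sex cell such as 'ASD.F'")
  structure(list(roi_voxels = matrix(as.integer(roi_voxels), ncol = 3),
                 target_domain = target_domain,
                 coupling_r = coupling_r, apply_to = apply_to),
            class = "coupling_spec")
}

.roi_linear_idx <- function(roi_voxels, dm) {
  bad <- roi_voxels[, 1] < 1 | roi_voxels[, 1] > dm[1] |
    roi_voxels[, 2] < 1 | roi_voxels[, 2] > dm[2] |
    roi_voxels[, 3] < 1 | roi_voxels[, 3] > dm[3]
  if (any(bad)) stop("ROI voxel outside the grid")
  roi_voxels[, 1] + dm[1] * (roi_voxels[, 2] - 1) +
    dm[1] * dm[2] * (roi_voxels[, 3] - 1)
}

#' Generate a synthetic gray-matter cohort with known ground truth
#'
#' Builds per-subject volumes as
#' `smooth(baseline + pattern terms + age slope + site shift + noise)`,
#' applies ROI-symptom couplings within their subgroups, and clamps at
#' zero (gray-matter volume maps are non-negative). Smoothing follows the
#' VBM order: effects are injected into the unsmoothed maps, then the
#' whole map is smoothed. Per-subject noise uses an RNG substream derived
#' from `(seed, subject index)`.
#'
#' @param spec a [cohort_spec()]; the symptom table is generated from it.
#' @param grid_shape integer length-3 (default desk-scale 32^3).
#' @param voxel_size mm per voxel (default 3 mm isotropic).
#' @param mask logical array; default [ellipsoid_mask()] on the grid.
#' @param patterns list of [pattern_spec()].
#' @param couplings list of [coupling_spec()].
#' @param baseline mean GM value inside the volume.
#' @param noise_sd SD of the iid voxel noise (GM units, before smoothing).
#' @param smooth_fwhm smoothing kernel FWHM in mm.
#' @param age_slope GM change per year of age (global).
#' @param gm_site_sd SD of the per-site additive GM shift.
#' @param dir optional output directory: volumes, mask, symptom TSV and a
#'   JSON ground-truth sidecar are written there.
#' @return list with elements `cohort` ([gm_cohort()]), `table`
#'   (`symptom_table`) and `ground_truth` (list of implanted effects).
#' @export
generate_gm_cohort <- function(spec, grid_shape = c(32, 32, 32),
                               voxel_size = c(3, 3, 3), mask = NULL,
                               patterns = list(), couplings = list(),
                               baseline = 0.5, noise_sd = 0.1,
                               smooth_fwhm = 6, age_slope = -0.002,
                               gm_site_sd = 0, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (inherits(patterns, "pattern_spec")) patterns <- list(patterns)
  if (inherits(couplings, "coupling_spec")) couplings <- list(couplings)
  if (is.null(mask)) mask <- ellipsoid_mask(grid_shape)
  if (!identical(dim(mask), as.integer(grid_shape)) &&
      !identical(dim(mask), grid_shape))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match grid ", paste(grid_shape, collapse = "x"))
  dm <- dim(mask)
  V <- prod(dm)
  mask_lin <- which(mask)

  for (p in patterns)
    if (!all(.roi_linear_idx(p$roi_voxels, dm) %in% mask_lin))
      stop("pattern ROI contains out-of-mask voxels")
  for (cp in couplings)
    if (!all(.roi_linear_idx(cp$roi_voxels, dm) %in% mask_lin))
      stop("coupling ROI contains out-of-mask voxels")

  table <- generate_symptom_cohort(spec)
  n <- nrow(table)
  cell <- paste(table$group, table$sex, sep = ".")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.subject_seed(spec$seed, 0L, stream = 2L))
  site_gm_shift <- rnorm(spec$n_sites, 0, gm_site_sd)
  site_idx <- as.integer(sub("site", "", as.character(table$site)))

  # per-pattern random latents for covariance mode: balanced +/-1 within
  # each contrast-level cell, so realized per-voxel cell means are exactly
  # zero and univariate maps stay null in every finite sample
  pat_latent <- lapply(seq_along(patterns), function(pi) {
    p <- patterns[[pi]]
    set.seed(.subject_seed(spec$seed, pi, stream = 3L))
    z <- numeric(n)
    carriers <- if (is.null(p$within)) rep(TRUE, n)
    else as.character(table$group) == p$within
    for (lev in levels(table[[p$contrast]])) {
      idx <- which(carriers & table[[p$contrast]] == lev)
      m <- length(idx)
      if (!m) next
      signs <- rep(c(1, -1), length.out = m)
      z[idx] <- signs[sample.int(m)]
    }
    z
  })

  data <- matrix(0, V, n)
  age_c <- table$age - mean(table$age)
  for (s in seq_len(n)) {
    set.seed(.subject_seed(spec$seed, s, stream = 4L))
    vol <- rnorm(V, 0, noise_sd)
    vol <- vol + baseline + age_slope * age_c[s] + site_gm_shift[site_idx[s]]
    for (pi in seq_along(patterns)) {
      p <- patterns[[pi]]
      if (!is.null(p$within) && as.character(table$group[s]) != p$within) next
      idx <- .roi_linear_idx(p$roi_voxels, dm)
      lev <- levels(table[[p$contrast]])
      first <- as.character(table[[p$contrast]][s]) == lev[1]
      if (p$effect_type == "mean-shift") {
        vol[idx] <- vol[idx] + (if (first) 0.5 else -0.5) * p$amplitude
      } else {
        # covariance pattern: equal-sign halves in class 1, opposite in class 2
        half1 <- p$roi_voxels[, 1] <= stats::median(p$roi_voxels[, 1])
        z <- pat_latent[[pi]][s] * p$amplitude
        vol[idx[half1]] <- vol[idx[half1]] + z
        vol[idx[!half1]] <- vol[idx[!half1]] + (if (first) z else -z)
      }
    }
    data[, s] <- vol
  }

  cohort <- gm_cohort(data, mask, voxel_size = voxel_size,
                      subject_ids = table$subject_id)
  cohort <- gaussian_smooth_fwhm(cohort, smooth_fwhm)

  gt_couplings <- list()
  for (ci in seq_along(couplings)) {
    cp <- couplings[[ci]]
    idx <- .roi_linear_idx(cp$roi_voxels, dm)
    ind <- array(0, dm); ind[idx] <- 1
    ind_sm <- gaussian_smooth_fwhm(ind, smooth_fwhm, cohort$voxel_size)
    kappa <- mean(ind_sm[idx])
    sel <- cell == cp$apply_to
    if (sum(sel) < 3) stop("apply_to subgroup '", cp$apply_to,
                           "' has fewer than 3 subjects")
    roi_mean <- colMeans(cohort$data[idx, sel, drop = FALSE])
    score <- table[[cp$target_domain]][sel]
    if (sd(score) == 0) stop("target domain scores are constant in subgroup")
    z <- as.numeric(scale(score))
    s_resid <- sd(roi_mean)
    slope <- s_resid * cp$coupling_r / sqrt(1 - cp$coupling_r^2)
    add <- as.numeric(ind_sm) / kappa
    cohort$data[, sel] <- cohort$data[, sel] +
      outer(add, slope * z)
    gt_couplings[[ci]] <- list(roi_voxels = cp$roi_voxels,
                               target_domain = cp$target_domain,
                               coupling_r = cp$coupling_r,
                               apply_to = cp$apply_to, slope = slope)
  }
  cohort$data <- pmax(cohort$data, 0)

  ground_truth <- list(
    patterns = lapply(patterns, function(p)
      list(roi_voxels = p$roi_voxels, effect_type = p$effect_type,
           amplitude = p$amplitude, contrast = p$contrast,
           within = p$within)),
    couplings = gt_couplings,
    seed = spec$seed, grid_shape = dm, smooth_fwhm = smooth_fwhm,
    noise_sd = noise_sd, baseline = baseline)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gm_cohort(cohort, dir)
    write_symptom_table(table, file.path(dir, "symptoms.tsv"))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, table = table, ground_truth = ground_truth)
}

#' Cuboid ROI voxel list
#'
#' Convenience helper: all voxels of an axis-aligned box, as a k x 3
#' 1-based index matrix (for building [pattern_spec()] / [coupling_spec()]
#' ROIs).
#'
#' @param from,to integer length-3 corners (inclusive).
#' @return k x 3 integer matrix.
#' @export
box_roi <- function(from, to) {
  as.matrix(expand.grid(i = from[1]:to[1], j = from[2]:to[2],
                        k = from[3]:to[3]))
}
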