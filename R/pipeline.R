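# End-to-end pipeline: generate (or load) a cohort, run symptom
# statistics, univariate maps, the searchlight with binomial + extent
# inference, and the brain-behavior SVR, writing a reproducible report
# bundle to one run directory.

#' Default pipeline configuration
#'
#' Returns the full configuration list of [run_pipeline()] with the
#' default synthetic study: an imaging cohort of 25/25 ASD girls/boys and
#' 19/19 TD girls/boys on a desk-scale 32^3 grid with an implanted
#' covariance pattern separating the sexes within ASD and one ROI-RRB
#' coupling in ASD girls. Any element can be overridden via the `config`
#' argument of [run_pipeline()].
#'
#' @param seed root seed; all stage seeds derive from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = file.path(tempdir(), sprintf("dimorph_run_%d", seed)),
    stages = list(generate = TRUE, symptoms = TRUE, univariate = TRUE,
                  searchlight = TRUE, svr = TRUE),
    cohort = list(preset = "abide", grid_shape = c(32, 32, 32),
                  voxel_size = c(3, 3, 3), noise_sd = 0.1,
                  smooth_fwhm = 6, gm_site_sd = 0.02,
                  pattern = list(from = c(13, 13, 13), to = c(18, 18, 18),
                                 effect_type = "covariance-pattern",
                                 amplitude = 0.25, contrast = "sex",
                                 within = "ASD"),
                  coupling = list(center_vox = c(16, 16, 16), radius_mm = 8,
                                  target_domain = "adi_rrb",
                                  coupling_r = 0.8, apply_to = "ASD.F")),
    searchlight = list(half_width = 1, M = 10,
                       C_grid = c(0.125, 0.25, 0.5, 2, 16, 32),
                       alpha_grid = c(0.125, 0.25, 0.5, 2, 16, 32),
                       min_in_mask = 14, height_p = 0.001,
                       cluster_p = 0.01, fwe = "bonferroni", n_sims = 500,
                       smoothness_fwhm = 2),
    svr = list(radius_mm = 8, n_perm = 200, domain = "adi_rrb",
               subgroups = c("ASD.F", "ASD.M")))
}

.read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_pipeline_config(seed = if (!is.null(config$seed)) config$seed else 1L)
  modifyList(base, config)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> symptom statistics -> univariate maps ->
#' searchlight -> cluster table -> brain-behavior SVR on a synthetic (or
#' user-supplied) cohort, writing every stage product plus a consolidated
#' JSON summary under `config$out_dir`. The configuration (with the root
#' seed) fully determines every output file. A failing stage aborts with
#' the stage name; products of earlier stages are kept.
#'
#' @param config configuration list (see [default_pipeline_config()]), or
#'   the path of a YAML/JSON file holding one. Partial lists are merged
#'   over the defaults.
#' @return (invisibly) a list with the stage results: `table`, `cohort`,
#'   `symptoms`, `univariate`, `searchlight`, `clusters`, `svr`, `paths`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- .read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  res <- list(paths = list(out_dir = cfg$out_dir))

  if (isTRUE(cfg$stages$generate)) {
    logf("stage generate")
    res <- c(res, .stage("generate", {
      cc <- cfg$cohort
      spec <- if (identical(cc$preset, "ndar")) ndar_cohort_spec(seed = cfg$seed)
      else abide_cohort_spec(seed = cfg$seed)
      patterns <- list()
      if (!is.null(cc$pattern))
        patterns <- list(pattern_spec(box_roi(cc$pattern$from, cc$pattern$to),
                                      effect_type = cc$pattern$effect_type,
                                      amplitude = cc$pattern$amplitude,
                                      contrast = cc$pattern$contrast,
                                      within = cc$pattern$within))
      couplings <- list()
      if (!is.null(cc$coupling)) {
        mask0 <- ellipsoid_mask(cc$grid_shape)
        aff0 <- .default_affine(cc$grid_shape, cc$voxel_size)
        ctr <- as.numeric(voxel_to_world(aff0, matrix(cc$coupling$center_vox, 1)))
        sph <- sphere_roi_voxels(ctr, cc$coupling$radius_mm, mask0, aff0)
        couplings <- list(coupling_spec(sph$voxels,
                                        target_domain = cc$coupling$target_domain,
                                        coupling_r = cc$coupling$coupling_r,
                                        apply_to = cc$coupling$apply_to))
      }
      gen <- generate_gm_cohort(spec, grid_shape = cc$grid_shape,
                                voxel_size = cc$voxel_size,
                                patterns = patterns, couplings = couplings,
                                noise_sd = cc$noise_sd,
                                smooth_fwhm = cc$smooth_fwhm,
                                gm_site_sd = cc$gm_site_sd,
                                dir = file.path(cfg$out_dir, "cohort"))
      list(table = gen$table, cohort = gen$cohort,
           ground_truth = gen$ground_truth)
    }))
  }
  tab <- res$table
  asd <- tab[tab$group == "ASD", ]

  if (isTRUE(cfg$stages$symptoms)) {
    logf("stage symptoms")
    res$symptoms <- .stage("symptoms", {
      tt <- domain_ttests(asd, grouping = "sex")
      an_age <- if (nlevels(droplevels(tab$group)) == 2)
        demographic_anova(tab, dv = "age") else NULL
      an_iq <- if (nlevels(droplevels(tab$group)) == 2)
        demographic_anova(tab, dv = "iq") else NULL
      clf <- sparse_classifier_loocv(asd, label = "sex", seed = cfg$seed)
      write.table(tt, file.path(cfg$out_dir, "symptom_ttests.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(ttests = tt, anova_age = an_age, anova_iq = an_iq,
           classifier = clf)
    })
  }

  if (isTRUE(cfg$stages$univariate) && !is.null(res$cohort)) {
    logf("stage univariate")
    res$univariate <- .stage("univariate", {
      asd_idx <- which(tab$group == "ASD")
      sub <- res$cohort
      sub$data <- sub$data[, asd_idx, drop = FALSE]
      sub$subject_ids <- sub$subject_ids[asd_idx]
      tmap <- voxelwise_ttest(sub, asd$sex,
                              covs = asd[, c("age", "site")])
      amaps <- if (nlevels(droplevels(tab$group)) == 2)
        voxelwise_anova_2x2(res$cohort, tab$group, tab$sex,
                            covs = tab[, c("age", "site")]) else NULL
      list(ttest = tmap, anova = amaps)
    })
  }

  if (isTRUE(cfg$stages$searchlight) && !is.null(res$cohort)) {
    logf("stage searchlight")
    res$searchlight <- .stage("searchlight", {
      sl <- cfg$searchlight
      config_sl <- searchlight_config(half_width = sl$half_width,
                                      C_grid = sl$C_grid,
                                      alpha_grid = sl$alpha_grid, M = sl$M,
                                      seed = cfg$seed + 101L,
                                      min_in_mask = sl$min_in_mask)
      asd_idx <- which(tab$group == "ASD")
      sub <- res$cohort
      sub$data <- sub$data[, asd_idx, drop = FALSE]
      sub$subject_ids <- sub$subject_ids[asd_idx]
      ca <- searchlight_map(sub, asd$sex, covs = asd[, c("age", "site")],
                            config = config_sl)
      pmap <- binomial_pvalue_map(ca)
      ext <- monte_carlo_extent_threshold(sub$mask,
                                          smoothness_fwhm = sl$smoothness_fwhm,
                                          height_p = sl$height_p,
                                          cluster_p = sl$cluster_p,
                                          n_sims = sl$n_sims,
                                          seed = cfg$seed + 202L)
      clusters <- threshold_and_cluster(ca, pmap, ext, fwe_mode = sl$fwe)
      acc_img <- RNifti::asNifti(ifelse(is.na(ca$accuracy), 0, ca$accuracy))
      RNifti::qform(acc_img) <- structure(res$cohort$affine, code = 2L)
      RNifti::writeNifti(acc_img, file.path(cfg$out_dir, "ca_map.nii.gz"))
      p_img <- RNifti::asNifti(ifelse(is.na(pmap), 1, pmap))
      RNifti::qform(p_img) <- structure(res$cohort$affine, code = 2L)
      RNifti::writeNifti(p_img, file.path(cfg$out_dir, "binomial_p.nii.gz"))
      write.table(clusters, file.path(cfg$out_dir, "clusters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(ca_map = ca, p_map = pmap, extent = ext, clusters = clusters)
    })
    res$clusters <- res$searchlight$clusters
  }

  if (isTRUE(cfg$stages$svr)) {
    logf("stage svr")
    res$svr <- .stage("svr", {
      if (is.null(res$clusters))
        stop("no cluster table available: run (or supply) the searchlight stage first")
      if (!nrow(res$clusters)) {
        logf("  no surviving clusters; SVR skipped")
        NULL
      } else {
        sv <- cfg$svr
        out <- lapply(sv$subgroups, function(sg)
          cbind(subgroup = sg,
                svr_brainbehavior(res$cohort, tab, res$clusters,
                                  domain = sv$domain, subgroup = sg,
                                  radius_mm = sv$radius_mm,
                                  n_perm = sv$n_perm,
                                  seed = cfg$seed + 303L)))
        out <- do.call(rbind, out)
        write.table(out, file.path(cfg$out_dir, "svr_results.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out
      }
    })
  }

  logf("writing summary")
  summary <- list(
    seed = cfg$seed,
    n_subjects = nrow(tab),
    symptom_ttests = if (!is.null(res$symptoms)) res$symptoms$ttests,
    classifier_accuracy = if (!is.null(res$symptoms))
      res$symptoms$classifier$loocv_accuracy,
    classifier_selected = if (!is.null(res$symptoms))
      res$symptoms$classifier$selected_features,
    n_clusters = if (!is.null(res$clusters)) nrow(res$clusters),
    extent_k_min = if (!is.null(res$searchlight)) res$searchlight$extent$k_min,
    svr = if (!is.null(res$svr) && is.data.frame(res$svr))
      res$svr[, c("subgroup", "roi", "r2", "p_perm", "p_fdr")])
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(res)
}
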