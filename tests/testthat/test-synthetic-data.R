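# Synthetic cohort generator: determinism, size contracts, effect-size
# recovery, nuisance structure, and the implanted-pattern ground truth.

test_that("symptom cohort is deterministic and extensible by subject substreams", {
  spec <- cohort_spec(c(ASD.F = 10, ASD.M = 10), seed = 42)
  t1 <- generate_symptom_cohort(spec)
  t2 <- generate_symptom_cohort(spec)
  expect_identical(t1, t2)
  t3 <- generate_symptom_cohort(cohort_spec(c(ASD.F = 10, ASD.M = 10), seed = 43))
  expect_false(identical(t1$adi_rrb, t3$adi_rrb))
  # first cell's subjects unchanged when the second cell grows
  t4 <- generate_symptom_cohort(cohort_spec(c(ASD.F = 10, ASD.M = 20), seed = 42))
  expect_identical(t1[1:10, c("age", "iq", "adi_rrb")],
                   t4[1:10, c("age", "iq", "adi_rrb")])
})

test_that("minimal cohort has the contracted size and finite scores", {
  tab <- generate_symptom_cohort(cohort_spec(2, seed = 1))
  expect_equal(nrow(tab), 8)  # 2 per cell x 4 cells
  expect_true(all(is.finite(tab$adi_total)))
  expect_true(all(tab$adi_total >= 0))
  expect_true(all(tab$adi_total >= tab$adi_rrb))
  expect_false(anyDuplicated(tab$subject_id) > 0)
})

test_that("cohort spec rejects invalid designs", {
  expect_error(cohort_spec(c(ASD.F = 1, ASD.M = 10)), ">= 2")
  expect_error(cohort_spec(c(bad = 5)), "group.sex|form")
  expect_error(cohort_spec(5, domain_effects = c(nonsense = 1)), "unknown domain")
  expect_error(cohort_spec(5, age_range = c(13, 7)), "min < max")
})

test_that("null domain effects give calibrated t-test p-values over seeds", {
  hits <- vapply(1:200, function(s) {
    tab <- generate_symptom_cohort(cohort_spec(c(ASD.F = 30, ASD.M = 30), seed = s))
    tt <- domain_ttests(tab, grouping = "sex", domains = "adi_social")
    tt$p < 0.05
  }, logical(1))
  # binomial 99% CI around 0.05 for 200 draws: [0.013, 0.095]
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.105)
})

test_that("requested RRB effect size is recovered at large n", {
  tab <- generate_symptom_cohort(
    cohort_spec(c(ASD.F = 500, ASD.M = 500),
                domain_effects = c(adi_rrb = 0.5), seed = 7))
  x1 <- tab$adi_rrb[tab$sex == "F"]; x2 <- tab$adi_rrb[tab$sex == "M"]
  d <- (mean(x1) - mean(x2)) / sqrt((var(x1) + var(x2)) / 2)
  expect_lt(abs(d - 0.5), 0.15)
  # domains without an effect stay near zero
  tt <- domain_ttests(tab, grouping = "sex", domains = c("adi_social", "adi_comm"))
  expect_true(all(abs(tt$t) < 4))
})

test_that("site variance fraction is recovered by one-way ANOVA", {
  spec <- cohort_spec(c(ASD.F = 200, ASD.M = 200), n_sites = 4,
                      site_effect_sd = 2.5, seed = 3)
  tab <- generate_symptom_cohort(spec)
  fit <- stats::aov(adi_social ~ site, data = tab)
  s <- summary(fit)[[1]]
  eta2 <- s[1, "Sum Sq"] / sum(s[, "Sum Sq"])
  # expected variance fraction ~ site_sd^2/(site_sd^2 + score_sd^2) = 0.148
  expect_gt(eta2, 0.05)
  expect_lt(eta2, 0.30)
})

test_that("gm cohort generation is deterministic and validates ROIs", {
  spec <- cohort_spec(c(ASD.F = 3, ASD.M = 3), seed = 5)
  g1 <- generate_gm_cohort(spec, grid_shape = c(10, 10, 10))
  g2 <- generate_gm_cohort(spec, grid_shape = c(10, 10, 10))
  expect_identical(g1$cohort$data, g2$cohort$data)
  expect_true(all(g1$cohort$data >= 0))
  out_roi <- matrix(c(1, 1, 1), 1)  # grid corner: outside the ellipsoid mask
  expect_error(generate_gm_cohort(spec, grid_shape = c(10, 10, 10),
                                  patterns = list(pattern_spec(out_roi, "mean-shift", 1))),
               "out-of-mask")
  expect_error(generate_gm_cohort(spec, grid_shape = c(10, 10, 10),
                                  mask = ellipsoid_mask(c(8, 8, 8))),
               "does not match")
})

test_that("null gm cohort has ~5% of in-mask voxels at p < 0.05", {
  gen <- small_gm_cohort(seed = 9, grid = c(20, 20, 20),
                         n_per_cell = c(ASD.F = 20, ASD.M = 20))
  tm <- voxelwise_ttest(gen$cohort, gen$table$sex)
  frac <- mean(tm$p[tm$mask] < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("covariance pattern is univariate-null but multivoxel-separable", {
  roi <- box_roi(c(7, 7, 7), c(12, 12, 12))
  pat <- pattern_spec(roi, "covariance-pattern", amplitude = 0.2,
                      contrast = "sex")
  gen <- small_gm_cohort(seed = 13, grid = c(18, 18, 18),
                         n_per_cell = c(ASD.F = 25, ASD.M = 25),
                         patterns = list(pat), noise_sd = 0.1)
  idx <- dimorphMVPA:::.roi_linear_idx(roi, gen$cohort$dim)
  tm <- voxelwise_ttest(gen$cohort, gen$table$sex)
  # per-voxel t statistics inside the ROI centered on zero
  expect_lt(abs(mean(tm$stat[idx])), 0.5)
  expect_lt(mean(abs(tm$stat[idx])), 1.5)
  # multivoxel classifier on the ROI: amplitude = 2 x noise_sd -> CA > 0.8
  X <- t(gen$cohort$data[idx, ])
  g <- gridsearch_cv_accuracy(X, gen$table$sex, searchlight_config(seed = 2))
  expect_gt(g$ca, 0.8)
})

test_that("ROI-symptom coupling holds in its subgroup and nowhere else", {
  sph <- center_sphere(grid = c(24, 24, 24), center_vox = c(12, 12, 12))
  cpl <- coupling_spec(sph$voxels, "adi_rrb", 0.9, "ASD.F")
  gen <- small_gm_cohort(seed = 17, grid = c(24, 24, 24),
                         couplings = list(cpl))
  cellv <- paste(gen$table$group, gen$table$sex, sep = ".")
  rmean <- colMeans(gen$cohort$data[sph$idx, ])
  r_in <- cor(rmean[cellv == "ASD.F"], gen$table$adi_rrb[cellv == "ASD.F"])
  expect_gte(r_in, 0.7)
  for (cl in c("ASD.M", "TD.F", "TD.M")) {
    r_out <- cor(rmean[cellv == cl], gen$table$adi_rrb[cellv == cl])
    expect_lte(abs(r_out), 0.45)
  }
})

test_that("cohort writes round-trip through NIfTI bit-identically", {
  gen <- small_gm_cohort(seed = 21, grid = c(10, 10, 10),
                         n_per_cell = c(ASD.F = 2, ASD.M = 2))
  dir <- withr::local_tempdir()
  write_gm_cohort(gen$cohort, dir)
  write_symptom_table(gen$table, file.path(dir, "symptoms.tsv"))
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  back <- read_gm_cohort(manifest, file.path(dir, "mask.nii.gz"),
                         table = gen$table)
  expect_equal(back$data, gen$cohort$data, tolerance = 1e-12)
  expect_identical(back$subject_ids, gen$cohort$subject_ids)
  tab <- read_symptom_table(file.path(dir, "symptoms.tsv"))
  expect_equal(tab$adi_rrb, gen$table$adi_rrb)
})
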