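# Searchlight engine: feature extraction, grid-search CV, map generation
# with oracle equivalence, binomial inference, Monte-Carlo extent
# calibration, clustering, and ROI transfer.

test_that("searchlight vectors have fixed length with zero-padding at edges", {
  gen <- small_gm_cohort(seed = 1, grid = c(8, 8, 8),
                         n_per_cell = c(ASD.F = 3, ASD.M = 3))
  cfg <- searchlight_config()
  ctr <- c(4, 4, 4)
  X <- extract_searchlight_vectors(gen$cohort, ctr, cfg)
  expect_equal(dim(X), c(6, 27))
  expect_equal(attr(X, "n_in_mask"), 27)
  # feature 14 is the center voxel (x fastest order)
  lin <- 4 + 8 * 3 + 64 * 3
  expect_equal(X[, 14], gen$cohort$data[lin, ])
  # half-width 0 degenerates to the single center voxel
  X0 <- extract_searchlight_vectors(gen$cohort, ctr,
                                    searchlight_config(half_width = 0))
  expect_equal(ncol(X0), 1)
  # an edge-of-mask voxel: padded features are exactly zero
  edge <- which(gen$cohort$mask, arr.ind = TRUE)
  edge <- edge[which.min(edge[, 1]), ]
  Xe <- extract_searchlight_vectors(gen$cohort, edge, cfg)
  expect_lt(attr(Xe, "n_in_mask"), 27)
  expect_true(all(Xe[, !attr(Xe, "validity")] == 0))
  expect_error(extract_searchlight_vectors(gen$cohort, c(1, 1, 1), cfg),
               "not in the mask")
})

test_that("well-separated classes reach high CV accuracy; contradictions bound it", {
  set.seed(2)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 27, -1.5), n / 2),
             matrix(rnorm(n / 2 * 27, 1.5), n / 2))
  y <- factor(rep(c("F", "M"), each = n / 2))
  g <- gridsearch_cv_accuracy(X, y, searchlight_config(seed = 3))
  expect_gte(g$ca, 0.95)
  # one subject duplicated into both classes can never be fully correct
  X2 <- rbind(X, X[1, , drop = FALSE])
  y2 <- factor(c(as.character(y), "M"))
  g2 <- gridsearch_cv_accuracy(X2, y2, searchlight_config(seed = 3))
  expect_lte(g2$ca, n / (n + 1))
})

test_that("grid ties break toward smallest C then smallest alpha", {
  counts <- matrix(5L, 3, 4)
  expect_equal(dimorphMVPA:::.grid_argmax(counts), c(1, 1))
  counts[2, 3] <- 7L; counts[3, 1] <- 7L
  expect_equal(dimorphMVPA:::.grid_argmax(counts), c(2, 3))
})

test_that("permuted labels give near-chance CA with the documented optimism", {
  set.seed(4)
  cas <- vapply(1:25, function(s) {
    X <- matrix(rnorm(40 * 27), 40)
    y <- factor(rep(c("F", "M"), 20))
    gridsearch_cv_accuracy(X, y, searchlight_config(seed = s))$ca
  }, numeric(1))
  # max over a 36-point grid inflates the null mean above 0.5; the bias
  # stays well below the binomial null threshold used for inference
  expect_gt(mean(cas), 0.45)
  expect_lt(mean(cas), 0.65)
})

test_that("searchlight map equals a literal nested-loop reimplementation", {
  gen <- small_gm_cohort(seed = 5, grid = c(5, 5, 5),
                         n_per_cell = c(ASD.F = 6, ASD.M = 6),
                         mask = array(TRUE, c(5, 5, 5)), smooth_fwhm = 0)
  cfg <- searchlight_config(M = 4, seed = 11, min_in_mask = 8)
  labels <- gen$table$sex
  map <- searchlight_map(gen$cohort, labels, config = cfg)

  # oracle: plain nested loops over voxels, folds and the grid, sharing
  # only the low-level single-fit routine and the fold assignment
  folds <- make_stratified_folds(labels, cfg$M, cfg$seed)
  y <- ifelse(labels == "F", 1L, -1L)
  dm <- gen$cohort$dim
  for (x in 1:5) for (yy in 1:5) for (z in 1:5) {
    feats <- extract_searchlight_vectors(gen$cohort, c(x, yy, z), cfg)
    if (attr(feats, "n_in_mask") < cfg$min_in_mask) {
      expect_true(is.na(map$accuracy[x, yy, z]))
      next
    }
    best <- -1; bestC <- NA; bestA <- NA
    for (C in cfg$C_grid) for (a in cfg$alpha_grid) {
      correct <- 0
      for (f in 1:cfg$M) {
        tr <- folds != f
        Xtr <- feats[tr, , drop = FALSE]; Xte <- feats[!tr, , drop = FALSE]
        mu <- colMeans(Xtr); sig <- apply(Xtr, 2, sd)
        for (j in seq_along(sig)) {
          if (sig[j] < 1e-12) { Xtr[, j] <- 0; Xte[, j] <- 0 }
          else {
            Xtr[, j] <- (Xtr[, j] - mu[j]) / sig[j]
            Xte[, j] <- (Xte[, j] - mu[j]) / sig[j]
          }
        }
        dec <- dimorphMVPA:::.svc_fit_decision_cpp(Xtr, y[tr], Xte, C, a)
        correct <- correct + sum(ifelse(dec > 0, 1L, -1L) == y[!tr])
      }
      ca <- correct / length(y)
      if (ca > best) { best <- ca; bestC <- C; bestA <- a }
    }
    expect_equal(map$accuracy[x, yy, z], best)
    expect_equal(map$best_C[x, yy, z], bestC)
    expect_equal(map$best_alpha[x, yy, z], bestA)
  }
})

test_that("searchlight map is deterministic and a 1-voxel mask evaluates 1 voxel", {
  gen <- small_gm_cohort(seed = 6, grid = c(6, 6, 6),
                         n_per_cell = c(ASD.F = 5, ASD.M = 5))
  cfg <- searchlight_config(M = 5, seed = 7, min_in_mask = 1)
  m1 <- searchlight_map(gen$cohort, gen$table$sex, config = cfg)
  m2 <- searchlight_map(gen$cohort, gen$table$sex, config = cfg)
  expect_identical(m1$accuracy, m2$accuracy)
  one <- gen$cohort
  one$mask <- array(FALSE, one$dim); one$mask[3, 3, 3] <- TRUE
  m3 <- searchlight_map(one, gen$table$sex, config = cfg)
  expect_equal(sum(!is.na(m3$accuracy)), 1)
})

test_that("binomial p map equals exact tail enumeration", {
  # direct tail sums, including the worked k = 8, N = 10 case: 56/1024
  ca <- structure(list(accuracy = array(0.8, c(1, 1, 1)), n_subjects = 10,
                       chance = 0.5), class = "ca_map")
  p <- binomial_pvalue_map(ca)
  expect_equal(p[1, 1, 1], 56 / 1024, tolerance = 1e-12)
  # k = 0 -> p = 1; k = N -> chance^N
  ca$accuracy[1, 1, 1] <- 0
  expect_equal(binomial_pvalue_map(ca)[1, 1, 1], 1)
  ca$accuracy[1, 1, 1] <- 1
  ca$n_subjects <- 50
  expect_equal(binomial_pvalue_map(ca)[1, 1, 1], 2^-50, tolerance = 1e-12)
  # full enumeration oracle for all k, N <= 20 (spot of the <= 64 sweep
  # exercised in the acceptance suite)
  for (N in c(7, 16, 20)) {
    caN <- structure(list(accuracy = array((0:N) / N, c(N + 1, 1, 1)),
                          n_subjects = N, chance = 0.5), class = "ca_map")
    pm <- binomial_pvalue_map(caN)
    for (k in 0:N) {
      exact <- sum(choose(N, k:N)) / 2^N
      expect_equal(pm[k + 1, 1, 1], exact, tolerance = 1e-12)
    }
  }
})

test_that("extent threshold: fwhm monotonicity and height monotonicity", {
  mask <- ellipsoid_mask(c(12, 12, 12))
  k0 <- monte_carlo_extent_threshold(mask, 0, height_p = 0.05,
                                     cluster_p = 0.05, n_sims = 400, seed = 1)
  k2 <- monte_carlo_extent_threshold(mask, 2, height_p = 0.05,
                                     cluster_p = 0.05, n_sims = 400, seed = 1)
  k4 <- monte_carlo_extent_threshold(mask, 4, height_p = 0.05,
                                     cluster_p = 0.05, n_sims = 400, seed = 1)
  expect_lte(k0$k_min, k2$k_min)
  expect_lte(k2$k_min, k4$k_min)
  # stricter height -> smaller clusters -> k_min cannot grow
  k_strict <- monte_carlo_extent_threshold(mask, 2, height_p = 0.005,
                                           cluster_p = 0.05, n_sims = 400,
                                           seed = 1)
  expect_lte(k_strict$k_min, k2$k_min)
})

test_that("fwhm = 0 extent threshold matches a brute-force enumeration", {
  mask <- array(TRUE, c(4, 4, 4))
  ext <- monte_carlo_extent_threshold(mask, 0, height_p = 0.05,
                                      cluster_p = 0.01, n_sims = 20000,
                                      seed = 2)
  # independent oracle: literal per-simulation flood fill in R
  set.seed(77)
  u <- qnorm(0.95)
  max_sizes <- vapply(1:20000, function(s) {
    supra <- array(rnorm(64) > u, c(4, 4, 4))
    best <- 0; seen <- array(FALSE, c(4, 4, 4))
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      if (!supra[i, j, k] || seen[i, j, k]) next
      queue <- list(c(i, j, k)); seen[i, j, k] <- TRUE; size <- 0
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]; size <- size + 1
        for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                       c(0,0,1), c(0,0,-1))) {
          w <- v + d
          if (any(w < 1) || any(w > 4)) next
          if (supra[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
            seen[w[1], w[2], w[3]] <- TRUE
            queue <- c(queue, list(w))
          }
        }
      }
      best <- max(best, size)
    }
    best
  }, numeric(1))
  kk <- 1:max(max_sizes)
  p_ge <- vapply(kk, function(k) mean(max_sizes >= k), numeric(1))
  k_oracle <- kk[which(p_ge <= 0.01)[1]]
  expect_equal(ext$k_min, k_oracle)
})

test_that("clustering respects the extent boundary exactly", {
  dm <- c(10, 10, 10)
  acc <- array(NA_real_, dm); p <- array(NA_real_, dm)
  mask <- array(TRUE, dm)
  acc[mask] <- 0.5; p[mask] <- 1
  # a 3-voxel line and a 4-voxel line of significant voxels
  p[2:4, 2, 2] <- 1e-9; acc[2:4, 2, 2] <- 0.9
  p[6:9, 6, 6] <- 1e-9; acc[6:9, 6, 6] <- c(0.91, 0.95, 0.93, 0.9)
  ca <- structure(list(accuracy = acc, n_subjects = 20, chance = 0.5,
                       mask = mask, affine = diag(4),
                       config = searchlight_config()),
                  class = "ca_map")
  tab <- threshold_and_cluster(ca, p, extent = 4L, fwe_mode = "none",
                               height_p = 0.001)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_voxels, 4)
  expect_equal(tab$peak_accuracy_pct, 95)
  # peak coordinate is the argmax voxel, in world mm (0-based affine)
  expect_equal(c(tab$peak_i, tab$peak_j, tab$peak_k), c(7, 6, 6))
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z), c(6, 5, 5))
  tab3 <- threshold_and_cluster(ca, p, extent = 3L, fwe_mode = "none",
                                height_p = 0.001)
  expect_equal(nrow(tab3), 2)
  # empty suprathreshold set -> empty table
  p[p < 1] <- 1
  tab0 <- threshold_and_cluster(ca, p, extent = 3L, fwe_mode = "none")
  expect_equal(nrow(tab0), 0)
})

test_that("ROI transfer: discovery ROI transfers within itself, null elsewhere", {
  roi <- box_roi(c(6, 6, 6), c(10, 10, 10))
  pat <- pattern_spec(roi, "covariance-pattern", amplitude = 0.25,
                      contrast = "sex", within = "ASD")
  gen <- small_gm_cohort(seed = 8, grid = c(16, 16, 16), patterns = list(pat))
  sub <- asd_subset(gen)
  cfg <- searchlight_config(seed = 5)
  roi_mask <- array(FALSE, c(16, 16, 16))
  roi_mask[roi] <- TRUE
  res <- roi_transfer_classification(sub$cohort, sub$table$sex,
                                     list(pattern = roi_mask), config = cfg)
  expect_gt(res$accuracy, 0.8)
  expect_lt(res$p_binomial, 0.001)
  # same ROI on the TD cohort (no implanted pattern there): null band
  td <- gen$table$group == "TD"
  tdc <- gen$cohort
  tdc$data <- tdc$data[, td]; tdc$subject_ids <- tdc$subject_ids[td]
  res_td <- roi_transfer_classification(tdc, droplevels(gen$table$sex[td]),
                                        list(pattern = roi_mask), config = cfg)
  expect_gt(res_td$p_binomial, 0.01)
  # 1-voxel ROI degenerates to univariate classification
  one <- array(FALSE, c(16, 16, 16)); one[8, 8, 8] <- TRUE
  res1 <- roi_transfer_classification(sub$cohort, sub$table$sex,
                                      list(uni = one), config = cfg)
  expect_equal(res1$n_voxels, 1)
  expect_error(roi_transfer_classification(sub$cohort, sub$table$sex,
                                           list(empty = array(FALSE, c(16, 16, 16))),
                                           config = cfg), "empty")
})
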