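# Searchlight MVPA engine: neighborhood feature extraction, grid-searched
# RBF-SVM M-fold cross-validation at every mask voxel, binomial inference
# on accuracy, Monte-Carlo cluster-extent calibration, cluster reporting,
# and cross-cohort ROI transfer.

#' Searchlight configuration
#'
#' @param half_width neighborhood half-width in voxels; 1 gives the
#'   classical 3x3x3 searchlight (27 features).
#' @param C_grid,alpha_grid positive grids for the SVM regularization
#'   parameter C and the RBF kernel width alpha (the coefficient in
#'   `K(x, y) = exp(-alpha ||x - y||^2)`). Default is the six-point grid
#'   {0.125, 0.25, 0.5, 2, 16, 32} for both.
#' @param M number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment (one assignment is
#'   drawn per run and shared across voxels, so spatial variation in
#'   accuracy is never confounded with fold noise).
#' @param min_in_mask minimum in-mask neighbors for a voxel to be
#'   evaluated; voxels below it are skipped and recorded.
#' @param standardize z-score features with training-fold statistics.
#' @param connectivity cluster connectivity for reporting: 6 (faces,
#'   default), 18 or 26.
#' @return object of class `searchlight_config`.
#' @export
searchlight_config <- function(half_width = 1L,
                               C_grid = c(0.125, 0.25, 0.5, 2, 16, 32),
                               alpha_grid = c(0.125, 0.25, 0.5, 2, 16, 32),
                               M = 10L, seed = 1L, min_in_mask = 14L,
                               standardize = TRUE, connectivity = 6L) {
  if (!length(C_grid) || !length(alpha_grid)) stop("empty parameter grid")
  if (any(C_grid <= 0) || any(alpha_grid <= 0)) stop("grids must be positive")
  if (is.unsorted(C_grid) || is.unsorted(alpha_grid))
    stop("grids must be sorted increasingly")
  if (M < 2) stop("M must be >= 2")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(half_width = as.integer(half_width), C_grid = C_grid,
                 alpha_grid = alpha_grid, M = as.integer(M),
                 seed = as.integer(seed), min_in_mask = as.integer(min_in_mask),
                 standardize = isTRUE(standardize),
                 connectivity = as.integer(connectivity)),
            class = "searchlight_config")
}

#' Searchlight neighborhood offsets
#'
#' Offsets of the cubic neighborhood in fixed feature order: the x offset
#' varies fastest, then y, then z (offset (0,0,0) is the center and, for
#' half-width 1, feature 14 of 27).
#'
#' @param half_width neighborhood half-width in voxels.
#' @return k x 3 integer matrix of voxel offsets.
#' @export
searchlight_offsets <- function(half_width = 1L) {
  r <- -half_width:half_width
  as.matrix(expand.grid(dx = r, dy = r, dz = r))
}

#' Extract searchlight feature vectors at one voxel
#'
#' One feature vector per subject from the cubic neighborhood centered at
#' `center`. Neighbors outside the grid or mask contribute a constant 0
#' feature (zero-padding keeps the dimensionality fixed across voxels);
#' the attached `validity` attribute marks which features are real.
#'
#' @param cohort a [gm_cohort()].
#' @param center length-3 1-based voxel index; must be in-mask.
#' @param config a [searchlight_config()].
#' @return n x k numeric matrix with attributes `validity` (logical k) and
#'   `n_in_mask`.
#' @export
extract_searchlight_vectors <- function(cohort, center, config = searchlight_config()) {
  dm <- cohort$dim
  if (!cohort$mask[center[1], center[2], center[3]]) stop("center voxel is not in the mask")
  off <- searchlight_offsets(config$half_width)
  pos <- sweep(off, 2, as.integer(center), "+")
  inside <- pos[, 1] >= 1 & pos[, 1] <= dm[1] &
    pos[, 2] >= 1 & pos[, 2] <= dm[2] &
    pos[, 3] >= 1 & pos[, 3] <= dm[3]
  lin <- rep(NA_integer_, nrow(off))
  lin[inside] <- pos[inside, 1] + dm[1] * (pos[inside, 2] - 1) +
    dm[1] * dm[2] * (pos[inside, 3] - 1)
  valid <- inside
  valid[inside] <- cohort$mask[lin[inside]]
  X <- matrix(0, ncol(cohort$data), nrow(off))
  X[, valid] <- t(cohort$data[lin[valid], , drop = FALSE])
  attr(X, "validity") <- valid
  attr(X, "n_in_mask") <- sum(valid)
  X
}

# map a two-level factor to +1 (first level) / -1 (second level)
.labels_pm1 <- function(labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  ifelse(labels == levels(labels)[1], 1L, -1L)
}

#' Stratified cross-validation folds
#'
#' Random fold assignment stratified by class (and optionally site), drawn
#' from `seed`. Errors if any training fold would lose a class entirely.
#'
#' @param labels two-level factor.
#' @param M number of folds.
#' @param seed integer.
#' @param strata optional extra stratification factor (e.g. site).
#' @return integer vector of fold ids 1..M.
#' @export
make_stratified_folds <- function(labels, M, seed = 1L, strata = NULL) {
  labels <- droplevels(factor(labels))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- .stratified_fold_ids(labels, M, strata = strata)
  for (f in seq_len(M)) {
    tr <- labels[fold != f]
    if (length(unique(tr)) < 2)
      stop("class absent from the training set of fold ", f,
           "; reduce M or rebalance")
  }
  fold
}

#' Grid-searched M-fold CV accuracy of the RBF-SVM
#'
#' Trains an RBF-kernel SVM at every `(C, alpha)` grid point with M-fold
#' cross-validation and returns the maximal cross-validation accuracy
#' (CA), i.e. total correct test predictions over all folds divided by n.
#' Grid ties are broken toward the smallest C, then the smallest alpha.
#'
#' @param features n x d numeric matrix.
#' @param labels two-level factor (first level is coded +1).
#' @param config a [searchlight_config()].
#' @param folds optional fold assignment (1..M); drawn from `config$seed`
#'   when omitted.
#' @return list: `ca`, `best_C`, `best_alpha`, `accuracy_grid`
#'   (C x alpha), `n`, `folds`.
#' @export
gridsearch_cv_accuracy <- function(features, labels, config = searchlight_config(),
                                   folds = NULL) {
  y <- .labels_pm1(labels)
  n <- nrow(features)
  if (n < config$M) stop("fewer subjects than folds")
  if (is.null(folds)) folds <- make_stratified_folds(labels, config$M, config$seed)
  res <- .svm_grid_cv_cpp(as.matrix(features), y, as.integer(folds - 1L),
                          config$M, config$C_grid, config$alpha_grid,
                          config$standardize)
  acc <- res$correct / res$n
  best <- .grid_argmax(res$correct)
  list(ca = acc[best[1], best[2]], best_C = config$C_grid[best[1]],
       best_alpha = config$alpha_grid[best[2]],
       accuracy_grid = matrix(acc, nrow = length(config$C_grid),
                              dimnames = list(C = config$C_grid,
                                              alpha = config$alpha_grid)),
       n = res$n, folds = folds)
}

# argmax over the (C x alpha) count matrix with ties toward smallest C,
# then smallest alpha (C scanned in the outer loop)
.grid_argmax <- function(counts) {
  best <- -1L; bc <- 1L; bg <- 1L
  for (ci in seq_len(nrow(counts)))
    for (gi in seq_len(ncol(counts)))
      if (counts[ci, gi] > best) { best <- counts[ci, gi]; bc <- ci; bg <- gi }
  c(bc, bg)
}

#' Searchlight classification-accuracy map
#'
#' Runs the grid-searched M-fold RBF-SVM at every in-mask voxel with at
#' least `min_in_mask` in-mask neighbors, using one fold assignment shared
#' across voxels. Covariates, if given, are removed from the whole sample
#' by voxelwise regression before classification (set
#' `covariate_mode = "fold"` to re-estimate the nuisance fit inside each
#' training fold instead, which is leakage-free but departs from the
#' global-residualization convention of classical VBM tooling).
#'
#' @param cohort a [gm_cohort()].
#' @param labels two-level factor per subject.
#' @param covs optional covariate data frame (`age`, `site`, ...).
#' @param config a [searchlight_config()].
#' @param covariate_mode `"global"` (default) or `"fold"`.
#' @return a `ca_map` list: `accuracy` (3-D array; NA where skipped or
#'   out of mask), `best_C`/`best_alpha` arrays, `n_in_mask` array,
#'   `n_subjects`, `chance`, `folds`, `mask`, `affine`, `config`.
#' @export
searchlight_map <- function(cohort, labels, covs = NULL,
                            config = searchlight_config(),
                            covariate_mode = c("global", "fold")) {
  covariate_mode <- match.arg(covariate_mode)
  labels <- droplevels(factor(labels))
  y <- .labels_pm1(labels)
  n <- ncol(cohort$data)
  if (length(y) != n) stop("labels length does not match cohort")
  folds <- make_stratified_folds(labels, config$M, config$seed)
  if (!is.null(covs) && covariate_mode == "global")
    cohort <- residualize_covariates(cohort, covs)
  if (!is.null(covs) && covariate_mode == "fold")
    cohort <- .residualize_per_fold(cohort, covs, folds)
  off <- searchlight_offsets(config$half_width)
  res <- .searchlight_cpp(cohort$data, as.integer(cohort$dim),
                          as.integer(cohort$mask), as.matrix(off), y,
                          as.integer(folds - 1L), config$M,
                          config$C_grid, config$alpha_grid,
                          config$min_in_mask, config$standardize)
  shape <- cohort$dim
  structure(list(accuracy = array(res$ca, shape),
                 best_C = array(res$bestC, shape),
                 best_alpha = array(res$bestG, shape),
                 n_in_mask = array(res$n_in_mask, shape),
                 n_subjects = n,
                 chance = max(table(labels)) / n,
                 folds = folds, mask = cohort$mask, affine = cohort$affine,
                 config = config),
            class = "ca_map")
}

# leakage-free variant: nuisance coefficients estimated on each training
# fold and applied to the fold's test subjects; returns a list of per-fold
# residualized cohorts collapsed into one (test rows taken from their fold)
.residualize_per_fold <- function(cohort, covs, folds) {
  X <- .nuisance_design(covs, ncol(cohort$data))
  Y <- t(cohort$data[cohort$mask, , drop = FALSE])
  # each subject's row is residualized under the nuisance fit estimated on
  # the folds that exclude it, so held-out data never inform the fit
  out <- Y
  for (f in sort(unique(folds))) {
    tr <- folds != f
    qx <- qr(X[tr, , drop = FALSE])
    if (qx$rank < ncol(X)) stop("nuisance design rank-deficient within fold ", f)
    B <- qr.coef(qx, Y[tr, , drop = FALSE])
    out[!tr, ] <- Y[!tr, , drop = FALSE] - X[!tr, , drop = FALSE] %*% B
  }
  cohort$data[cohort$mask, ] <- t(out)
  cohort
}

#' @export
print.ca_map <- function(x, ...) {
  ev <- sum(!is.na(x$accuracy))
  cat("ca_map:", ev, "evaluated voxels,", x$n_subjects, "subjects, chance",
      sprintf("%.3f", x$chance), "\n")
  if (ev) cat("accuracy range:",
              sprintf("%.3f-%.3f", min(x$accuracy, na.rm = TRUE),
                      max(x$accuracy, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Binomial p-value map for a classification-accuracy map
#'
#' Under the null hypothesis of exchangeable group labels the number of
#' correct cross-validation predictions is modeled as Binomial(N, chance);
#' the map holds the one-sided upper-tail probability
#' `P(X >= k)` with `k = round(CA * N)` at every evaluated voxel.
#'
#' @param ca_map a `ca_map` from [searchlight_map()].
#' @param chance success probability under the null (defaults to the
#'   majority-class proportion stored in the map).
#' @return 3-D array of p-values (NA where the map is NA), with attributes
#'   `n` and `chance`.
#' @export
binomial_pvalue_map <- function(ca_map, chance = NULL) {
  if (is.null(chance)) chance <- ca_map$chance
  N <- ca_map$n_subjects
  k <- round(ca_map$accuracy * N)
  if (any(k > N, na.rm = TRUE)) stop("accuracy implies more correct than N")
  p <- array(pbinom(k - 1, N, chance, lower.tail = FALSE), dim(k))
  attr(p, "n") <- N
  attr(p, "chance") <- chance
  p
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates `n_sims` Gaussian noise fields on the full grid, smooths them
#' to the stated FWHM, standardizes by the theoretical post-smoothing SD,
#' thresholds at the `height_p` upper quantile inside the mask, and
#' records the maximal suprathreshold cluster size per simulation. The
#' extent threshold `k_min` is the smallest cluster size whose null
#' probability of occurring anywhere in the mask is at most `cluster_p`
#' (the AlphaSim construction).
#'
#' @param mask logical 3-D array.
#' @param smoothness_fwhm assumed map smoothness, in voxels (isotropic) or
#'   length-3.
#' @param height_p voxel-level threshold probability.
#' @param cluster_p cluster-level probability.
#' @param n_sims number of simulated null fields.
#' @param seed integer.
#' @param connectivity 6, 18 or 26.
#' @return an `extent_threshold` list: `k_min`, `height_p`, `cluster_p`,
#'   `n_sims`, `smoothness_fwhm`, `null_max_size` (the simulated maximal
#'   cluster sizes).
#' @export
monte_carlo_extent_threshold <- function(mask, smoothness_fwhm = 0,
                                         height_p = 0.001, cluster_p = 0.01,
                                         n_sims = 1000, seed = 1L,
                                         connectivity = 6L) {
  stopifnot(height_p > 0, height_p < 1, cluster_p > 0, cluster_p < 1,
            n_sims >= 1)
  dm <- dim(mask)
  fw <- rep(smoothness_fwhm, length.out = 3)
  if (any(fw > dm)) warning("smoothness FWHM exceeds the mask extent")
  sig <- fw / (2 * sqrt(2 * log(2)))
  kerns <- lapply(sig, .gauss_kernel_1d)
  sd_theory <- prod(vapply(kerns, function(k) sqrt(sum(k^2)), numeric(1)))
  u <- qnorm(1 - height_p) * sd_theory
  V <- prod(dm)
  mask_vec <- as.logical(mask)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  max_sizes <- integer(n_sims)
  chunk <- max(1L, min(n_sims, as.integer(2e7 / V)))
  done <- 0L
  while (done < n_sims) {
    m <- min(chunk, n_sims - done)
    supra <- matrix(FALSE, V, m)
    for (s in seq_len(m)) {
      field <- array(rnorm(V), dm)
      if (any(sig > 0)) for (ax in 1:3) field <- .axis_conv(field, kerns[[ax]], ax)
      supra[, s] <- (as.numeric(field) > u) & mask_vec
    }
    max_sizes[done + seq_len(m)] <-
      .max_cluster_batch_cpp(supra, as.integer(dm), as.integer(connectivity))
    done <- done + m
  }
  kk <- seq_len(max(max_sizes, 1L))
  p_ge <- vapply(kk, function(k) mean(max_sizes >= k), numeric(1))
  k_min <- if (any(p_ge <= cluster_p)) kk[which(p_ge <= cluster_p)[1]]
  else max(max_sizes) + 1L
  k_min <- max(k_min, 1L)
  structure(list(k_min = as.integer(k_min), height_p = height_p,
                 cluster_p = cluster_p, n_sims = as.integer(n_sims),
                 smoothness_fwhm = smoothness_fwhm,
                 null_max_size = max_sizes, connectivity = connectivity),
            class = "extent_threshold")
}

#' @export
print.extent_threshold <- function(x, ...) {
  cat("extent threshold: k_min =", x$k_min, "voxels (height p", x$height_p,
      ", cluster p", x$cluster_p, ",", x$n_sims, "simulations, FWHM",
      paste(x$smoothness_fwhm, collapse = "x"), "voxels)\n")
  invisible(x)
}

#' Threshold a CA map and report surviving clusters
#'
#' Voxels surviving the (optionally familywise-corrected) height threshold
#' are grouped into connected clusters; clusters smaller than the
#' Monte-Carlo extent threshold are dropped. Each surviving cluster is
#' reported with its size, the world (mm) coordinate of its peak-accuracy
#' voxel, and the peak accuracy in percent.
#'
#' @param ca_map a `ca_map`.
#' @param p_map binomial p array from [binomial_pvalue_map()].
#' @param extent an `extent_threshold`, or an integer `k_min`.
#' @param fwe_mode `"bonferroni"` (corrects the voxel p over the evaluated
#'   voxels), `"none"`, or `"permutation"` (requires `null_max_ca`, the
#'   maximal-CA null distribution from label permutations).
#' @param height_p height threshold applied to the (corrected) p.
#' @param null_max_ca numeric vector of maximal CA values under label
#'   permutation (for `fwe_mode = "permutation"`).
#' @return a `data.frame` (the cluster table): `cluster, n_voxels,
#'   peak_x, peak_y, peak_z, peak_accuracy_pct, peak_p, peak_i/j/k`.
#' @export
threshold_and_cluster <- function(ca_map, p_map, extent,
                                  fwe_mode = c("bonferroni", "none", "permutation"),
                                  height_p = NULL, null_max_ca = NULL) {
  fwe_mode <- match.arg(fwe_mode)
  k_min <- if (inherits(extent, "extent_threshold")) extent$k_min else as.integer(extent)
  if (is.null(height_p))
    height_p <- if (inherits(extent, "extent_threshold")) extent$height_p else 0.001
  if (!identical(dim(ca_map$accuracy), dim(p_map)))
    stop("accuracy and p maps are on different grids")
  evaluated <- !is.na(ca_map$accuracy)
  n_eval <- sum(evaluated)
  supra <- array(FALSE, dim(p_map))
  if (fwe_mode == "bonferroni") {
    supra[evaluated] <- pmin(p_map[evaluated] * n_eval, 1) <= height_p
  } else if (fwe_mode == "none") {
    supra[evaluated] <- p_map[evaluated] <= height_p
  } else {
    if (is.null(null_max_ca)) stop("permutation FWE needs null_max_ca")
    ca_crit <- quantile(null_max_ca, 1 - height_p, type = 1)
    supra[evaluated] <- ca_map$accuracy[evaluated] >= ca_crit
  }
  conn <- if (!is.null(ca_map$config)) ca_map$config$connectivity else 6L
  lab <- array(.label_clusters_cpp(as.integer(supra), as.integer(dim(supra)),
                                   as.integer(conn)), dim(supra))
  out <- list()
  row <- 0L
  if (max(lab) > 0) {
    for (cl in seq_len(max(lab))) {
      idx <- which(lab == cl)
      if (length(idx) < k_min) next
      acc <- ca_map$accuracy[idx]
      pk <- idx[which.max(acc)]
      ijk <- arrayInd(pk, dim(lab))
      w <- voxel_to_world(ca_map$affine, ijk)
      row <- row + 1L
      out[[row]] <- data.frame(
        cluster = row, n_voxels = length(idx),
        peak_x = w[1], peak_y = w[2], peak_z = w[3],
        peak_accuracy_pct = 100 * max(acc), peak_p = p_map[pk],
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3])
    }
  }
  tab <- if (row) do.call(rbind, out)
  else data.frame(cluster = integer(), n_voxels = integer(),
                  peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
                  peak_accuracy_pct = numeric(), peak_p = numeric(),
                  peak_i = integer(), peak_j = integer(), peak_k = integer())
  tab <- tab[order(-tab$n_voxels), , drop = FALSE]
  if (nrow(tab)) tab$cluster <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "k_min") <- k_min
  attr(tab, "fwe_mode") <- fwe_mode
  attr(tab, "height_p") <- height_p
  tab
}

#' Maximal-CA null distribution from label permutations
#'
#' Reruns the searchlight on permuted labels and records the maximal CA
#' over the mask for each permutation: the max-statistic null for
#' permutation-based FWE control.
#'
#' @param cohort,labels,covs,config as in [searchlight_map()].
#' @param n_perm number of permutations.
#' @param seed integer.
#' @return numeric vector of length `n_perm`.
#' @export
searchlight_null_max_ca <- function(cohort, labels, covs = NULL,
                                    config = searchlight_config(),
                                    n_perm = 100, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perms <- replicate(n_perm, sample(length(labels)))
  vapply(seq_len(n_perm), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    m <- searchlight_map(cohort, labels[perms[, i]], covs = covs, config = cfg)
    max(m$accuracy, na.rm = TRUE)
  }, numeric(1))
}

#' Cross-cohort ROI transfer classification
#'
#' For each ROI discovered in one cohort/contrast, classifies the two
#' classes of another cohort using all ROI voxels as one feature vector,
#' with the same grid-searched M-fold CV as the searchlight, and reports
#' the accuracy with its binomial p-value.
#'
#' @param cohort target cohort (a [gm_cohort()]).
#' @param labels two-level factor in the target cohort.
#' @param roi_masks named list of ROI definitions: logical 3-D arrays or
#'   k x 3 voxel index matrices on the shared grid.
#' @param config a [searchlight_config()].
#' @param covs optional covariates, removed globally before CV.
#' @return `data.frame`: `roi, n_voxels, accuracy, p_binomial, best_C,
#'   best_alpha`.
#' @export
roi_transfer_classification <- function(cohort, labels, roi_masks,
                                        config = searchlight_config(),
                                        covs = NULL) {
  labels <- droplevels(factor(labels))
  if (!is.null(covs)) cohort <- residualize_covariates(cohort, covs)
  folds <- make_stratified_folds(labels, config$M, config$seed)
  n <- ncol(cohort$data)
  chance <- max(table(labels)) / n
  if (is.null(names(roi_masks)))
    names(roi_masks) <- paste0("roi", seq_along(roi_masks))
  rows <- lapply(names(roi_masks), function(nm) {
    r <- roi_masks[[nm]]
    idx <- if (is.matrix(r) && ncol(r) == 3) .roi_linear_idx(r, cohort$dim)
    else which(as.logical(r))
    if (!length(idx)) stop("ROI '", nm, "' is empty")
    X <- t(cohort$data[idx, , drop = FALSE])
    g <- gridsearch_cv_accuracy(X, labels, config, folds = folds)
    k <- round(g$ca * n)
    data.frame(roi = nm, n_voxels = length(idx), accuracy = g$ca,
               p_binomial = pbinom(k - 1, n, chance, lower.tail = FALSE),
               best_C = g$best_C, best_alpha = g$best_alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
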