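# Sphere-ROI support-vector regression of symptom severity on multivoxel
# gray-matter patterns: LOOCV R^2, permutation null, FDR across ROIs.

#' Sphere ROI on the voxel lattice
#'
#' All in-mask lattice points whose world-space centers lie within
#' `radius_mm` of `center_mm` (boundary ties included).
#'
#' @param center_mm world coordinate of the sphere center (length 3).
#' @param radius_mm sphere radius in mm (default 8, radius 0 selects the
#'   single nearest voxel containing the center).
#' @param mask logical 3-D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @return a `sphere_roi` list: `center`, `radius`, `voxels` (k x 3
#'   1-based indices), `idx` (linear indices).
#' @export
sphere_roi_voxels <- function(center_mm, radius_mm, mask, affine) {
  dm <- dim(mask)
  idx_all <- which(as.logical(mask))
  ijk <- arrayInd(idx_all, dm)
  w <- voxel_to_world(affine, ijk)
  d2 <- (w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
    (w[, 3] - center_mm[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9
  if (!any(keep)) stop("sphere at (", paste(signif(center_mm, 4), collapse = ", "),
                       ") with radius ", radius_mm, " mm contains no in-mask voxel")
  structure(list(center = center_mm, radius = radius_mm,
                 voxels = ijk[keep, , drop = FALSE],
                 idx = idx_all[keep]),
            class = "sphere_roi")
}

# kernel-width default: the median heuristic, 1 / median squared
# inter-subject distance (falls back to 1/(d * var) for degenerate data)
.svr_gamma_default <- function(X) {
  d2 <- as.numeric(stats::dist(X))^2
  m <- stats::median(d2)
  if (is.finite(m) && m > 0) return(1 / m)
  v <- var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

.svr_prepare <- function(features, scores, covs, standardize = TRUE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(scores) != n) stop("scores length does not match features")
  if (n < 3) stop("need at least 3 subjects for LOOCV SVR")
  if (sd(scores) == 0) stop("scores are constant: R^2 undefined")
  if (!is.null(covs)) {
    features <- residualize_covariates(features, covs)
    scores <- as.numeric(residualize_covariates(matrix(scores), covs))
  }
  if (standardize) {
    # the usual libsvm preprocessing (svm-scale): unit-variance features
    # and target, so the fixed (C, nu) budget is expressed on a common scale
    sds <- apply(features, 2, sd)
    sds[sds < 1e-12] <- 1
    features <- scale(features, scale = sds)
    scores <- as.numeric(scale(scores))
  }
  list(X = features, y = scores)
}

.r2_of <- function(obs, pred, method) {
  if (method == "pearson") {
    if (sd(pred) == 0) return(0)
    cor(obs, pred)^2
  } else {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
}

#' LOOCV R^2 of nu-SVR from ROI features
#'
#' Predicts symptom scores from multivoxel features with RBF-kernel
#' nu-support-vector regression (`C = 1`, `nu = 0.05` by default), each
#' subject predicted by a model trained on all others. R^2 defaults to the
#' explained-variance definition `1 - SSE/SST` on the LOOCV predictions
#' (negative when the model predicts worse than the mean, as is normal for
#' a null cross-validated model); `r2_method = "pearson"` gives the squared
#' Pearson correlation instead, which is sign-blind and can rank a
#' systematically anti-correlated null fit above a genuine one (see the
#' methods vignette). Covariates are residualized out of both features and
#' scores beforehand, and features and scores are then standardized
#' (`standardize = FALSE` disables this).
#'
#' @param features n x d numeric matrix (e.g. GM values of a sphere ROI).
#' @param scores numeric symptom scores.
#' @param covs optional covariate data frame (`age`, `site`).
#' @param C,nu SVR parameters.
#' @param gamma RBF kernel width; default is the median heuristic
#'   `1 / median(squared inter-subject distance)` on the prepared features.
#' @param r2_method `"ss"` (default, 1 - SSE/SST) or `"pearson"`.
#' @param standardize standardize features and scores after covariate
#'   removal (default `TRUE`).
#' @return list: `r2`, `predictions`, `settings`.
#' @export
svr_loocv_r2 <- function(features, scores, covs = NULL, C = 1, nu = 0.05,
                         gamma = NULL, r2_method = c("ss", "pearson"),
                         standardize = TRUE) {
  r2_method <- match.arg(r2_method)
  pr <- .svr_prepare(features, scores, covs, standardize)
  if (is.null(gamma)) gamma <- .svr_gamma_default(pr$X)
  pred <- .svr_loocv_multi_cpp(pr$X, matrix(pr$y), C, nu, gamma)[, 1]
  list(r2 = .r2_of(pr$y, pred, r2_method), predictions = pred,
       settings = list(C = C, nu = nu, gamma = gamma, r2_method = r2_method))
}

#' Permutation null for the LOOCV SVR R^2
#'
#' Generates surrogate datasets by permuting the score vector, recomputes
#' the LOOCV R^2 for each, and returns the permutation p-value by the
#' plain counting rule `p = #{R_i^2 > R^2} / n_perm` (strict inequality,
#' no add-one correction), together with the add-one estimator
#' `(1 + #{R_i^2 >= R^2}) / (n_perm + 1)` and the tie count. When
#' covariates are supplied, permuted score vectors are re-residualized on
#' the nuisance design (the Freedman-Lane scheme), which keeps the null
#' calibrated when features and scores share nuisance structure such as
#' small per-site cells.
#'
#' @param features,scores,covs,C,nu,gamma,r2_method as [svr_loocv_r2()].
#' @param n_perm number of surrogates (1000 in the reference procedure).
#' @param seed integer seed for the permutations.
#' @return an `svr_result` list: `r2`, `null_r2` (length `n_perm`),
#'   `p_perm`, `p_perm_add1`, `n_ties`, `settings`.
#' @export
permutation_null <- function(features, scores, covs = NULL, C = 1, nu = 0.05,
                             gamma = NULL, n_perm = 1000, seed = 1L,
                             r2_method = c("ss", "pearson"),
                             standardize = TRUE) {
  r2_method <- match.arg(r2_method)
  if (n_perm < 1) stop("n_perm must be >= 1")
  pr <- .svr_prepare(features, scores, covs, standardize)
  if (is.null(gamma)) gamma <- .svr_gamma_default(pr$X)
  n <- nrow(pr$X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  Y <- cbind(pr$y, matrix(pr$y[perms], n, n_perm))
  if (!is.null(covs)) {
    # surrogate scores are re-residualized on the nuisance design
    # (Freedman-Lane): a plain shuffle of residuals is not exchangeable
    # when features and scores share the same projection (e.g. small site
    # cells), which makes the naive null anti-conservative
    qx <- qr(.nuisance_design(covs, n))
    Y[, -1] <- qr.resid(qx, Y[, -1, drop = FALSE])
  }
  pred <- .svr_loocv_multi_cpp(pr$X, Y, C, nu, gamma)
  r2 <- .r2_of(pr$y, pred[, 1], r2_method)
  null_r2 <- vapply(seq_len(n_perm), function(i)
    .r2_of(Y[, i + 1], pred[, i + 1], r2_method), numeric(1))
  structure(list(r2 = r2, null_r2 = null_r2,
                 p_perm = mean(null_r2 > r2),
                 p_perm_add1 = (1 + sum(null_r2 >= r2)) / (n_perm + 1),
                 n_ties = sum(null_r2 == r2),
                 settings = list(C = C, nu = nu, gamma = gamma,
                                 r2_method = r2_method, n_perm = n_perm,
                                 seed = seed)),
            class = "svr_result")
}

#' @export
print.svr_result <- function(x, ...) {
  cat(sprintf("nu-SVR LOOCV R^2 = %.3f, permutation p = %.4g (%d surrogates)\n",
              x$r2, x$p_perm, length(x$null_r2)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), invariant to input
#' order up to the matching reorder.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and order as the input.
#' @export
fdr_correct <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Brain-behavior SVR across cluster-derived sphere ROIs
#'
#' For every cluster of a searchlight cluster table, centers a sphere at
#' the cluster's peak-accuracy voxel (the deterministic stand-in for
#' visual peak selection), extracts the in-mask sphere voxels, and runs
#' LOOCV nu-SVR of the chosen symptom domain with a permutation null,
#' within the requested subgroup. Raw permutation p-values are adjusted
#' across ROIs by Benjamini-Hochberg FDR.
#'
#' @param cohort a [gm_cohort()] (all subjects).
#' @param table matching `symptom_table`.
#' @param clusters cluster table from [threshold_and_cluster()], or a
#'   named list of `sphere_roi`/voxel-matrix ROIs.
#' @param domain symptom domain column to predict.
#' @param subgroup `group.sex` cell to analyze (e.g. `"ASD.F"`); `NULL`
#'   uses all subjects.
#' @param radius_mm sphere radius (default 8 mm).
#' @param covs covariate columns of `table` to residualize out (default
#'   age and site; set `NULL` for none).
#' @param n_perm,seed,C,nu,gamma,r2_method forwarded to the SVR stages.
#' @return `data.frame`: one row per ROI with `roi, n_voxels, r2, p_perm,
#'   p_perm_add1, p_fdr` plus the SVR settings.
#' @export
svr_brainbehavior <- function(cohort, table, clusters, domain = "adi_rrb",
                              subgroup = NULL, radius_mm = 8,
                              covs = c("age", "site"), n_perm = 1000,
                              seed = 1L, C = 1, nu = 0.05, gamma = NULL,
                              r2_method = c("ss", "pearson")) {
  r2_method <- match.arg(r2_method)
  if (!domain %in% names(table)) stop("no such domain column: ", domain)
  sel <- if (is.null(subgroup)) rep(TRUE, nrow(table))
  else paste(table$group, table$sex, sep = ".") == subgroup
  if (sum(sel) < 3) stop("subgroup '", subgroup, "' has fewer than 3 subjects")

  rois <- if (is.data.frame(clusters)) {
    if (!nrow(clusters)) return(data.frame(
      roi = character(), n_voxels = integer(), r2 = numeric(),
      p_perm = numeric(), p_perm_add1 = numeric(), p_fdr = numeric()))
    lapply(seq_len(nrow(clusters)), function(i)
      sphere_roi_voxels(c(clusters$peak_x[i], clusters$peak_y[i],
                          clusters$peak_z[i]),
                        radius_mm, cohort$mask, cohort$affine))
  } else clusters
  if (is.null(names(rois)) || !any(nzchar(names(rois))))
    names(rois) <- paste0("roi", seq_along(rois))

  cv <- if (!is.null(covs)) {
    cc <- as.data.frame(table[sel, covs, drop = FALSE])
    # a covariate constant within the subgroup carries no information
    keep <- vapply(cc, function(z) length(unique(z)) > 1, logical(1))
    if (any(keep)) droplevels(cc[, keep, drop = FALSE]) else NULL
  } else NULL

  scores <- table[[domain]][sel]
  rows <- lapply(names(rois), function(nm) {
    r <- rois[[nm]]
    idx <- if (inherits(r, "sphere_roi")) r$idx
    else if (is.matrix(r)) .roi_linear_idx(r, cohort$dim)
    else which(as.logical(r))
    X <- t(cohort$data[idx, sel, drop = FALSE])
    pn <- permutation_null(X, scores, covs = cv, C = C, nu = nu,
                           gamma = gamma, n_perm = n_perm, seed = seed,
                           r2_method = r2_method)
    data.frame(roi = nm, n_voxels = length(idx), r2 = pn$r2,
               p_perm = pn$p_perm, p_perm_add1 = pn$p_perm_add1,
               C = C, nu = nu, gamma = pn$settings$gamma,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_correct(out$p_perm)
  out
}
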